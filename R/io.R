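# CSV dialect used throughout: UTF-8, comma-separated, "." decimal point,
# mandatory header. Accession identifiers contain a comma, so the accession
# column must be quoted; write.csv quotes it by default.

measurement_columns <- c("species", "accession", "rooting_pct", "aa_rsa_pct",
                         "tpc_mgGAE_100g", "height_18m_m", "growth_rate_pct",
                         "fruit_onset_season", "genetically_distinct")

parse_logical_cell <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(NA)
  v <- tolower(trimws(x))
  if (v %in% c("true", "t", "1", "yes")) return(TRUE)
  if (v %in% c("false", "f", "0", "no")) return(FALSE)
  validation_error(sprintf("cannot parse '%s' as logical", x))
}

#' Read per-genotype raw measurements
#'
#' Reads a measurements CSV (columns `species`, `accession`, `rooting_pct`,
#' `aa_rsa_pct`, `tpc_mgGAE_100g`, `height_18m_m`, `growth_rate_pct`,
#' `fruit_onset_season`, `genetically_distinct`; empty cell = missing) into
#' validated [species_profile()] objects. Validation failures report the
#' offending data row.
#'
#' @param path path to the CSV file.
#' @return named list of [species_profile()] objects, one per species.
#' @export
read_measurements <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(measurement_columns, names(tab))
  if (length(missing) > 0)
    validation_error(sprintf("measurements file %s: missing column(s) %s",
                             path, paste(missing, collapse = ", ")))
  num <- function(x) if (is.na(x) || !nzchar(trimws(x))) NA_real_ else {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) validation_error(sprintf("non-numeric cell '%s'", x))
    v
  }
  genos <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    tryCatch(
      list(species = trimws(row$species),
           g = genotype_measurements(
             accession = row$accession,
             rooting_pct = num(row$rooting_pct),
             aa_rsa_pct = num(row$aa_rsa_pct),
             tpc = num(row$tpc_mgGAE_100g),
             height_18m = num(row$height_18m_m),
             growth_rate_6_18 = num(row$growth_rate_pct),
             fruit_onset_season = num(row$fruit_onset_season),
             genetically_distinct = parse_logical_cell(row$genetically_distinct))),
      nupeval_error = function(e)
        validation_error(sprintf("%s, data row %d: %s", path, i, conditionMessage(e))))
  })
  species <- vapply(genos, `[[`, character(1), "species")
  out <- lapply(split(genos, species), function(rows)
    species_profile(rows[[1]]$species, lapply(rows, `[[`, "g")))
  out[unique(species)]
}

#' Write per-genotype raw measurements
#'
#' Inverse of [read_measurements()]: serializes species profiles to the
#' documented CSV dialect (missing values as empty cells).
#'
#' @param profiles list of [species_profile()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(profiles, path) {
  if (inherits(profiles, "species_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(p$genotypes, function(g) {
      data.frame(species = p$species_name, accession = g$accession,
                 rooting_pct = g$rooting_pct, aa_rsa_pct = g$aa_rsa_pct,
                 tpc_mgGAE_100g = g$tpc, height_18m_m = g$height_18m,
                 growth_rate_pct = g$growth_rate_6_18,
                 fruit_onset_season = g$fruit_onset_season,
                 genetically_distinct = g$genetically_distinct,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format trial CSV
#'
#' Expects the [trial_dataset()] columns. Instead of
#' `months_after_planting`, an ISO-8601 `date` column may be supplied
#' together with `planting_date`; months are then computed as days since
#' planting / 30.4375 (the mean Gregorian month).
#'
#' @param path path to the CSV file.
#' @param planting_date optional ISO-8601 planting date (e.g. "2020-03-01").
#' @return a [trial_dataset()].
#' @export
read_trial_csv <- function(path, planting_date = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!is.null(planting_date) && "date" %in% names(tab)) {
    p0 <- as.Date(planting_date)
    if (is.na(p0)) validation_error("planting_date must be ISO-8601 (YYYY-MM-DD)")
    tab$months_after_planting <-
      as.numeric(as.Date(tab$date) - p0) / 30.4375
    tab$date <- NULL
  }
  trial_dataset(tab)
}

#' Write a trial dataset to CSV
#'
#' @param dataset a [trial_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "trial_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read feasibility score vectors
#'
#' Reads the attribute-by-species layout (rows = the 12 attributes, columns
#' = species, cells = integer scores; a trailing non-numeric column such as
#' data sources is ignored).
#'
#' @param path path to the CSV file.
#' @return named list: species -> named integer vector over the 12
#'   attributes.
#' @export
read_feasibility_scores <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!"attribute" %in% names(tab))
    validation_error(sprintf("%s: first column must be 'attribute'", path))
  species_cols <- setdiff(names(tab), "attribute")
  numeric_cols <- species_cols[vapply(tab[species_cols], function(col)
    all(!is.na(suppressWarnings(as.numeric(col)))), logical(1))]
  if (length(numeric_cols) == 0L)
    validation_error(sprintf("%s: no species score columns found", path))
  out <- lapply(numeric_cols, function(sp) {
    v <- as.numeric(tab[[sp]])
    names(v) <- trimws(tab$attribute)
    v
  })
  names(out) <- numeric_cols
  out
}

scale_to_list <- function(scale) {
  out <- list(attribute_id = scale$attribute_id, type = scale$type)
  if (scale$type == "numeric") {
    out$bands <- lapply(seq_len(nrow(scale$bands)), function(i) {
      b <- scale$bands[i, ]
      list(score = b$score,
           lower = if (is.infinite(b$lower)) ".inf" else b$lower,
           upper = if (is.infinite(b$upper)) ".inf" else b$upper,
           lower_closed = b$lower_closed, upper_closed = b$upper_closed)
    })
  }
  out
}

#' Read a rubric override from YAML
#'
#' The YAML file holds a list of scales, each with `attribute_id`, `type`
#' (`numeric`, `boolean` or `season`) and, for numeric scales, `bands` with
#' `score`, `lower`, `upper`, `lower_closed`, `upper_closed` (`.inf` for an
#' unbounded end). Attributes not present in the file keep their default
#' scale.
#'
#' @param path path to the YAML file.
#' @return named list of seven [attribute_scale] objects.
#' @export
read_rubric_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  scales <- default_scales()
  for (entry in spec) {
    id <- entry$attribute_id %||% validation_error("rubric entry without attribute_id")
    type <- entry$type %||% "numeric"
    if (type == "numeric") {
      bands <- do.call(rbind, lapply(entry$bands, function(b) {
        to_num <- function(x) if (identical(x, ".inf") || identical(x, "Inf"))
          Inf else as.numeric(x)
        data.frame(score = as.integer(b$score), lower = to_num(b$lower),
                   upper = to_num(b$upper),
                   lower_closed = isTRUE(b$lower_closed),
                   upper_closed = isTRUE(b$upper_closed))
      }))
      scales[[id]] <- attribute_scale(id, bands, type = "numeric")
    } else {
      scales[[id]] <- attribute_scale(id, type = type)
    }
  }
  scales[rubric_attributes()]
}

#' Write rubric scales to YAML
#'
#' @param scales named list of [attribute_scale] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rubric_yaml <- function(scales, path) {
  yaml::write_yaml(lapply(unname(scales), scale_to_list), path)
  invisible(path)
}

#' Read a readiness band table from YAML
#'
#' Expects a list of bands with `band`, `label`, `lower` (exclusive) and
#' `upper` (inclusive); `.inf` / `-.inf` for unbounded ends.
#'
#' @param path path to the YAML file.
#' @return band table data.frame as in [default_readiness_bands()].
#' @export
read_band_table <- function(path) {
  spec <- yaml::read_yaml(path)
  to_num <- function(x) {
    if (identical(x, ".inf")) return(Inf)
    if (identical(x, "-.inf")) return(-Inf)
    as.numeric(x)
  }
  tab <- do.call(rbind, lapply(spec, function(b) {
    data.frame(band = b$band, label = b$label, lower = to_num(b$lower),
               upper = to_num(b$upper), stringsAsFactors = FALSE)
  }))
  tab[order(-tab$lower), , drop = FALSE]
}

# provenance checksum of a configuration object (rubric or band table):
# md5 of its canonical JSON serialization
config_checksum <- function(object) {
  if (is.list(object) && all(vapply(object, inherits, logical(1), "attribute_scale")))
    object <- lapply(unname(object), scale_to_list)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(object, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
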