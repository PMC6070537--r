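#' Table schemas for delimited I/O
#'
#' The package's single CSV dialect: comma-separated, one header row
#' whose names carry the units (`column_name_unit`).  Known schemas:
#' `thermogram` (temperature_C, heat_flow_W_per_g), `force_curve`
#' (deformation_nm, force_nN), `circulation` (time_h, intensity,
#' animal_id, group), `organ_panel` (organ, mass_g, intensity, group,
#' time_h, animal_id), `radial_profile` (d_mid, mean_R_nucleus,
#' mean_orientation, n_samples).
#'
#' @param name Schema name.
#' @return List with `columns` (named character vector of types) and
#'   `monotone` (column required to be strictly increasing, or NA).
#' @export
table_schema <- function(name) {
  schemas <- list(
    thermogram = list(
      columns = c(temperature_C = "numeric", heat_flow_W_per_g = "numeric"),
      monotone = "temperature_C"),
    force_curve = list(
      columns = c(deformation_nm = "numeric", force_nN = "numeric"),
      monotone = "deformation_nm"),
    circulation = list(
      columns = c(time_h = "numeric", intensity = "numeric",
                  animal_id = "character", group = "character"),
      monotone = NA_character_),
    organ_panel = list(
      columns = c(organ = "character", mass_g = "numeric",
                  intensity = "numeric", group = "character",
                  time_h = "numeric", animal_id = "character"),
      monotone = NA_character_),
    radial_profile = list(
      columns = c(d_mid = "numeric", mean_R_nucleus = "numeric",
                  mean_orientation = "numeric", n_samples = "numeric"),
      monotone = "d_mid")
  )
  if (!name %in% names(schemas)) stop("unknown schema: ", name)
  schemas[[name]]
}

#' Read a validated delimited table
#'
#' Reads a CSV against a named schema: all schema columns must be
#' present with parseable values (errors name the column and row);
#' unknown extra columns are accepted with a warning; a declared
#' monotone column must be strictly increasing (per animal for the
#' circulation schema).
#'
#' @param path File path.
#' @param schema Schema name (see [table_schema()]).
#' @return A data.frame with the schema's column types.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  sc <- table_schema(schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = TRUE)
  if (nrow(raw) == 0) stop("schema error in ", path, ": no data rows")
  missing <- setdiff(names(sc$columns), names(raw))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), names(sc$columns))
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  out <- raw[names(sc$columns)]
  for (col in names(sc$columns)) {
    if (sc$columns[[col]] == "numeric") {
      v <- suppressWarnings(as.numeric(out[[col]]))
      bad <- which(is.na(v) & !is.na(out[[col]]) & out[[col]] != "NA")
      if (length(bad))
        stop("schema error in ", path, ": non-numeric value '",
             out[[col]][bad[1]], "' in column ", col, ", row ", bad[1])
      out[[col]] <- v
    }
  }
  if (!is.na(sc$monotone)) {
    groups <- if (schema == "circulation") out$animal_id else
      rep("all", nrow(out))
    for (g in unique(groups)) {
      v <- out[[sc$monotone]][groups == g]
      if (any(diff(v) <= 0))
        stop("schema error in ", path, ": column ", sc$monotone,
             " must be strictly increasing",
             if (schema == "circulation") paste0(" for animal ", g) else "")
    }
  }
  out
}

#' Write a table in the package CSV dialect
#'
#' @param x Data.frame whose columns match a schema (checked).
#' @param path Output path (directory created if needed).
#' @param schema Schema name.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, schema) {
  sc <- table_schema(schema)
  missing <- setdiff(names(sc$columns), names(x))
  if (length(missing))
    stop("cannot write: missing column(s) ", paste(missing, collapse = ", "))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x[names(sc$columns)], path, row.names = FALSE)
  invisible(path)
}

#' Provenance sidecar for an output artifact
#'
#' Writes `<path>.provenance.json` recording the seed, parameters and
#' package version so every stochastic output is reproducible.
#'
#' @param path Artifact the sidecar describes.
#' @param seed Master seed used.
#' @param params List of parameters (must be JSON-serializable).
#' @return Sidecar path, invisibly.
#' @export
write_provenance <- function(path, seed, params = list()) {
  sidecar <- paste0(path, ".provenance.json")
  jsonlite::write_json(
    list(artifact = basename(path), seed = seed, params = params,
         package = "crystalsome",
         version = as.character(utils::packageVersion("crystalsome"))),
    sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(sidecar)
}
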