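## table schema registry: required columns, readr types, row-level checks
assay_schemas <- function() {
  list(
    mvalues = list(
      cols = c(probe_id = "c", array_id = "c", M = "d"),
      check = function(df) {
        bad <- which(!is.finite(df$M))
        if (length(bad)) return(sprintf("non-finite M (line %d)", bad[[1]]))
        dup <- which(duplicated(df[, c("probe_id", "array_id")]))
        if (length(dup)) {
          return(sprintf("duplicated (probe_id, array_id) pair (line %d)",
                         dup[[1]]))
        }
        NULL
      }
    ),
    scheme_arrays = list(
      cols = c(array_id = "c", cy3_sample = "c", cy5_sample = "c"),
      check = function(df) {
        bad <- which(df$cy3_sample == df$cy5_sample)
        if (length(bad)) {
          return(sprintf("array with identical samples in both channels (line %d)",
                         bad[[1]]))
        }
        NULL
      }
    ),
    samples = list(
      cols = c(sample_id = "c", group = "c"),
      check = function(df) {
        dup <- which(duplicated(df$sample_id))
        if (length(dup)) return(sprintf("duplicate sample_id (line %d)", dup[[1]]))
        NULL
      }
    ),
    ct = list(
      cols = c(sample_id = "c", amplicon_id = "c", replicate = "i", ct = "d"),
      check = function(df) {
        bad <- which(df$ct <= 0)
        if (length(bad)) return(sprintf("non-positive ct (line %d)", bad[[1]]))
        NULL
      }
    ),
    efficiencies = list(
      cols = c(amplicon_id = "c", efficiency = "d"),
      check = function(df) {
        bad <- which(df$efficiency <= 0.5 | df$efficiency > 1.2)
        if (length(bad)) {
          return(sprintf("efficiency outside (0.5, 1.2] (line %d)", bad[[1]]))
        }
        NULL
      }
    ),
    taqman = list(
      cols = c(sample_id = "c", fam_dR = "d", vic_dR = "d",
               control_type = "c", phenotype = "c"),
      check = function(df) {
        bad <- which(df$fam_dR < 0 | df$vic_dR < 0)
        if (length(bad)) {
          return(sprintf("negative fluorescence (line %d)", bad[[1]]))
        }
        bad <- which(!df$control_type %in% c("none", "SS", "GG", "NTC"))
        if (length(bad)) return(sprintf("unknown control_type (line %d)", bad[[1]]))
        bad <- which(!df$phenotype %in% c("alive", "dead", "untested"))
        if (length(bad)) return(sprintf("unknown phenotype (line %d)", bad[[1]]))
        NULL
      }
    ),
    bioassay = list(
      cols = c(insecticide = "c", season = "c", pbo = "l",
               n_exposed = "i", n_dead = "i"),
      check = function(df) {
        bad <- which(df$n_dead < 0 | df$n_dead > df$n_exposed)
        if (length(bad)) {
          return(sprintf("n_dead outside [0, n_exposed] (line %d)", bad[[1]]))
        }
        NULL
      }
    ),
    dose = list(
      cols = c(line_id = "c", dose = "d", n = "i", n_survived = "i"),
      check = function(df) {
        bad <- which(df$dose <= 0)
        if (length(bad)) return(sprintf("non-positive dose (line %d)", bad[[1]]))
        bad <- which(df$n_survived < 0 | df$n_survived > df$n)
        if (length(bad)) {
          return(sprintf("n_survived outside [0, n] (line %d)", bad[[1]]))
        }
        NULL
      }
    ),
    hplc = list(
      cols = c(condition = "c", nadph = "l", replicate = "i",
               peak_area = "d"),
      check = function(df) {
        bad <- which(df$peak_area < 0)
        if (length(bad)) return(sprintf("negative peak_area (line %d)", bad[[1]]))
        NULL
      }
    ),
    probe2gene = list(
      cols = c(probe_id = "c", gene_id = "c"),
      check = function(df) NULL
    )
  )
}

#' Read and validate a pipeline table
#'
#' Reads a tab-delimited table and enforces its schema: required columns
#' and types, plus row-level invariants (ranges, uniqueness). Violations
#' raise errors naming the file, (data) line and column.
#'
#' @param path a TSV file path, or a data frame already in memory (then
#'   only validated).
#' @param schema_id one of `"mvalues"`, `"scheme_arrays"`, `"samples"`,
#'   `"ct"`, `"efficiencies"`, `"taqman"`, `"bioassay"`, `"dose"`,
#'   `"hplc"`, `"probe2gene"`.
#' @return a validated tibble.
#' @export
load_and_validate <- function(path, schema_id) {
  schemas <- assay_schemas()
  if (!schema_id %in% names(schemas)) {
    abort(sprintf("unknown schema '%s'.", schema_id))
  }
  sch <- schemas[[schema_id]]
  src <- if (is.character(path)) path else "<data frame>"
  if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("file not found: %s", path))
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    df <- tibble::as_tibble(path)
  }
  missing <- setdiff(names(sch$cols), names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s (schema '%s')",
                  src, paste(missing, collapse = ", "), schema_id))
  }
  ## coerce types
  for (col in names(sch$cols)) {
    df[[col]] <- switch(sch$cols[[col]],
      c = as.character(df[[col]]),
      d = as.numeric(df[[col]]),
      i = as.integer(df[[col]]),
      l = as.logical(df[[col]])
    )
    if (any(is.na(df[[col]]))) {
      abort(sprintf("%s: column '%s' has missing/uncoercible values (line %d)",
                    src, col, which(is.na(df[[col]]))[[1]]))
    }
  }
  msg <- sch$check(df)
  if (!is.null(msg)) abort(sprintf("%s: %s", src, msg))
  df
}

#' Write a pipeline table as TSV
#'
#' UTF-8, tab-delimited, `.` decimal; the package's only tabular on-disk
#' format.
#'
#' @param df data frame.
#' @param path output path (directories created as needed).
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
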