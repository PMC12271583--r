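#' Apply the dataset inclusion rules to a metadata table
#'
#' Filters candidate map/model entries the way the published dataset was
#' curated: (1) drop entries without a corresponding atomic biological
#' assembly; (2) drop entries missing a resolution determined by the FSC
#' 0.143 cut-off; (3) among entries sharing one assembly (same `pdb_id`),
#' keep a single representative. In addition only entries inside the
#' high-resolution window `[res_min, res_max]` are kept. The redundancy
#' winner is the entry with the best (lowest) reported resolution, ties
#' broken by lexicographically smallest `emdb_id`.
#'
#' @param records data frame with columns `emdb_id` (required), `pdb_id`,
#'   `resolution` (Angstrom), `has_assembly` (logical), and optionally
#'   `resolution_method` (free text; entries whose method does not mention
#'   "0.143" fail rule 2).
#' @param res_min,res_max inclusive resolution window in Angstrom
#'   (defaults 1 and 4).
#' @return The input as a tibble with two added columns: logical `kept` and
#'   character `rejection_reason` (`NA` for kept rows; `"rule1_no_assembly"`,
#'   `"rule2_no_fsc0143_resolution"`, `"window_resolution_out_of_range"` or
#'   `"rule3_redundant_pdb"` otherwise). Row order is preserved.
#' @export
curate_records <- function(records, res_min = 1.0, res_max = 4.0) {
  rec <- tibble::as_tibble(records)
  n <- nrow(rec)
  if (n == 0L) {
    return(dplyr::mutate(rec, kept = logical(0),
                         rejection_reason = character(0)))
  }
  if (!"pdb_id" %in% names(rec)) rec$pdb_id <- NA_character_
  if (!"has_assembly" %in% names(rec)) rec$has_assembly <- !is.na(rec$pdb_id)
  if (!"resolution" %in% names(rec)) rec$resolution <- NA_real_
  has_method <- "resolution_method" %in% names(rec)

  reason <- rep(NA_character_, n)

  r1 <- is.na(rec$pdb_id) | rec$pdb_id == "" | !isTRUE_vec(rec$has_assembly)
  reason[r1] <- "rule1_no_assembly"

  bad_method <- if (has_method) {
    !is.na(rec$resolution_method) & rec$resolution_method != "" &
      !grepl("0\\.?143", rec$resolution_method)
  } else rep(FALSE, n)
  r2 <- is.na(reason) & (is.na(rec$resolution) | bad_method)
  reason[r2] <- "rule2_no_fsc0143_resolution"

  rw <- is.na(reason) &
    (rec$resolution < res_min | rec$resolution > res_max)
  reason[rw] <- "window_resolution_out_of_range"

  # rule 3: one representative per pdb_id among survivors
  surv <- which(is.na(reason))
  if (length(surv) > 1L) {
    ord <- surv[order(rec$resolution[surv], rec$emdb_id[surv])]
    dup <- ord[duplicated(rec$pdb_id[ord])]
    reason[dup] <- "rule3_redundant_pdb"
  }

  dplyr::mutate(rec, kept = is.na(reason), rejection_reason = reason)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Curate a metadata CSV on disk
#'
#' Reads a metadata table with header
#' `emdb_id, pdb_id, resolution, has_assembly, resolution_method`, applies
#' [curate_records()] and writes the annotated table (with `kept` and
#' `rejection_reason` columns) back out.
#'
#' @param in_path,out_path CSV paths.
#' @inheritParams curate_records
#' @return The annotated tibble, invisibly.
#' @export
curate_csv <- function(in_path, out_path, res_min = 1.0, res_max = 4.0) {
  rec <- utils::read.csv(in_path, stringsAsFactors = FALSE)
  out <- curate_records(rec, res_min = res_min, res_max = res_max)
  utils::write.csv(out, out_path, row.names = FALSE, na = "")
  invisible(out)
}
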