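#' Differential expression of a treated instance against same-plate controls
#'
#' The reference encoding starts from the difference between a treated
#' instance's expression values and a per-probe summary (mean by default) of
#' all control instances on the same physical plate, which removes
#' plate-level technical effects.
#'
#' @param treated numeric vector of N expression values for the treated
#'   instance.
#' @param controls numeric matrix (N probes x controls) or a numeric vector
#'   for a single control, all from the same plate as `treated`.
#' @param aggregate how to summarize controls per probe: `"mean"` (default)
#'   or `"median"`.
#' @param plate_id optional plate label used in error messages.
#' @return Numeric vector of N differential values.
#' @export
#' @examples
#' differential_profile(c(2, 0, 1), cbind(c(1, 0, 1), c(1, 0, 3)))
differential_profile <- function(treated, controls,
                                 aggregate = c("mean", "median"),
                                 plate_id = NULL) {
  aggregate <- match.arg(aggregate)
  if (is.null(dim(controls))) controls <- matrix(controls, ncol = 1L)
  if (ncol(controls) == 0L) {
    stop("no control instances available",
         if (!is.null(plate_id)) paste0(" on plate '", plate_id, "'") else "")
  }
  if (nrow(controls) != length(treated)) {
    stop("length mismatch: treated has ", length(treated),
         " probes but controls have ", nrow(controls))
  }
  ctrl <- switch(aggregate,
                 mean   = rowMeans(controls),
                 median = apply(controls, 1L, stats::median))
  as.numeric(treated) - ctrl
}

#' Signed-rank transform of a differential expression profile
#'
#' The probe with the i-th smallest absolute differential value receives
#' absolute rank i (the largest |d| gets rank N), and each rank carries the
#' sign of its differential value. The result is always an exact signed
#' permutation of 1..N, which the scoring denominator relies on.
#'
#' Ties in |d| (including multiple exact zeros) are broken deterministically
#' by ascending probe index, and a zero differential is assigned a positive
#' sign; zeros therefore land at the lowest ranks where their contribution to
#' any score is minimal.
#'
#' @param d numeric vector of differential expression values (length N >= 1).
#' @return Integer vector of signed ranks; `sort(abs(result))` is `1:N`.
#' @export
#' @examples
#' signed_rank(c(0.5, -2, 1))  # +1 -3 +2
signed_rank <- function(d) {
  if (length(d) < 1L) stop("empty differential profile")
  if (anyNA(d)) stop("differential profile contains missing values")
  o <- order(abs(d), seq_along(d), method = "radix")
  r <- integer(length(d))
  r[o] <- seq_along(d)
  r[d < 0] <- -r[d < 0]
  r
}

#' Build a signed-rank reference database
#'
#' Converts a batch of expression instances into one reference profile per
#' non-control instance: differential expression against the same-plate
#' controls ([differential_profile()]) followed by the signed-rank transform
#' ([signed_rank()]). Control instances are consumed in the process and not
#' stored.
#'
#' @param values numeric matrix, probes x instances; `rownames` are probe ids
#'   and `colnames` are instance ids matching `meta$instance_id`.
#' @param meta data.frame with columns `instance_id`, `perturbagen`,
#'   `cell_line`, `dose`, `time`, `plate_id`, `is_control` (logical or 0/1).
#' @param control_aggregate per-probe control summary, `"mean"` or `"median"`.
#' @return A `ref_db` object: list with `probe_ids` (character, defines probe
#'   order), `ranks` (integer matrix, instances x probes, rows named by
#'   instance id) and `meta` (metadata of the non-control instances).
#' @export
build_database <- function(values, meta, control_aggregate = c("mean", "median")) {
  control_aggregate <- match.arg(control_aggregate)
  stopifnot(is.matrix(values), is.data.frame(meta))
  required <- c("instance_id", "perturbagen", "cell_line", "dose", "time",
                "plate_id", "is_control")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyNA(values)) stop("expression matrix contains missing values")
  meta$is_control <- as.logical(as.integer(as.numeric(meta$is_control)))
  if (is.null(colnames(values)))
    stop("expression matrix must have instance ids as column names")
  if (!setequal(colnames(values), meta$instance_id))
    stop("expression matrix columns and metadata instance_id do not match")
  meta <- meta[match(colnames(values), meta$instance_id), , drop = FALSE]
  probe_ids <- rownames(values)
  if (is.null(probe_ids)) probe_ids <- sprintf("probe%04d", seq_len(nrow(values)))
  if (anyDuplicated(probe_ids)) stop("probe ids are not unique")

  treated_idx <- which(!meta$is_control)
  if (!length(treated_idx)) stop("no non-control instances in input")

  # plates with treated instances but no controls are a hard error
  plates <- unique(meta$plate_id[treated_idx])
  ctrl_by_plate <- split(which(meta$is_control), meta$plate_id[meta$is_control])
  orphan <- plates[!plates %in% names(ctrl_by_plate)]
  if (length(orphan)) {
    bad <- meta$instance_id[treated_idx][meta$plate_id[treated_idx] %in% orphan]
    stop("plate(s) without controls: ", paste(orphan, collapse = ", "),
         "; affected instances: ", paste(bad, collapse = ", "))
  }

  ranks <- matrix(0L, nrow = length(treated_idx), ncol = nrow(values),
                  dimnames = list(meta$instance_id[treated_idx], probe_ids))
  for (pl in plates) {
    ctrl <- values[, ctrl_by_plate[[pl]], drop = FALSE]
    trt <- treated_idx[meta$plate_id[treated_idx] == pl]
    for (j in trt) {
      d <- differential_profile(values[, j], ctrl,
                                aggregate = control_aggregate, plate_id = pl)
      ranks[meta$instance_id[j], ] <- signed_rank(d)
    }
  }

  structure(list(probe_ids = probe_ids,
                 ranks = ranks,
                 meta = meta[treated_idx,
                             c("instance_id", "perturbagen", "cell_line",
                               "dose", "time", "plate_id"), drop = FALSE]),
            class = "ref_db")
}

#' @export
print.ref_db <- function(x, ...) {
  cat("Signed-rank reference database\n")
  cat("  probes:      ", length(x$probe_ids), "\n")
  cat("  profiles:    ", nrow(x$ranks), "\n")
  cat("  perturbagens:", length(unique(x$meta$perturbagen)), "\n")
  cat("  cell lines:  ", length(unique(x$meta$cell_line)), "\n")
  invisible(x)
}

#' Group reference profiles into treatment sets
#'
#' A treatment set is the group of instances sharing a perturbagen
#' (`mode = "by_drug"`), or a perturbagen and a cell line
#' (`mode = "by_drug_and_cell_line"`, the usual choice). The returned groups
#' always partition the database: every profile belongs to exactly one set.
#'
#' @param db a `ref_db`.
#' @param mode grouping mode.
#' @return Named list of character vectors of instance ids; names are set
#'   keys (`perturbagen` or `perturbagen|cell_line`), sorted.
#' @export
group_sets <- function(db, mode = c("by_drug_and_cell_line", "by_drug")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "ref_db"))
  if (!nrow(db$meta)) stop("database is empty")
  key <- if (mode == "by_drug") db$meta$perturbagen
         else paste(db$meta$perturbagen, db$meta$cell_line, sep = "|")
  sets <- split(db$meta$instance_id, key)
  sets[order(names(sets), method = "radix")]
}

# split a set key back into perturbagen / cell_line columns
parse_set_keys <- function(keys, mode) {
  if (mode == "by_drug") {
    data.frame(set_key = keys, perturbagen = keys, cell_line = NA_character_,
               stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(set_key = keys,
               perturbagen = vapply(parts, `[`, "", 1L),
               cell_line = vapply(parts, function(p) paste(p[-1L], collapse = "|"), ""),
               stringsAsFactors = FALSE)
  }
}

#' Subset a database to an approved-compound list
#'
#' Retains exactly the profiles whose perturbagen appears in `approved`
#' (e.g. a list of approved drugs). Matching is exact string equality;
#' set `case_fold = TRUE` to match case-insensitively. Case folding is off by
#' default to avoid silently merging distinct perturbagen labels.
#'
#' @param db a `ref_db`.
#' @param approved character vector of perturbagen names to keep.
#' @param case_fold match case-insensitively?
#' @return A `ref_db` with the retained profiles; probe ids unchanged.
#' @export
filter_by_compound_list <- function(db, approved, case_fold = FALSE) {
  stopifnot(inherits(db, "ref_db"), is.character(approved))
  pert <- db$meta$perturbagen
  keep <- if (case_fold) tolower(pert) %in% tolower(approved)
          else pert %in% approved
  if (!any(keep)) stop("no profiles remain after compound filtering")
  db$ranks <- db$ranks[keep, , drop = FALSE]
  db$meta <- db$meta[keep, , drop = FALSE]
  db
}

#' Save a reference database to a directory
#'
#' Layout: `probes.txt` (one probe id per line, order-defining),
#' `ranks.tsv.gz` (instances x N signed integer ranks, first column
#' `instance_id`) and `instances.tsv` (instance metadata). The format is
#' plain text, diff-able and platform-neutral.
#'
#' @param db a `ref_db`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_refdb <- function(db, dir) {
  stopifnot(inherits(db, "ref_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(db$probe_ids, file.path(dir, "probes.txt"))
  rk <- data.table::as.data.table(db$ranks)
  rk <- cbind(data.table::data.table(instance_id = rownames(db$ranks)), rk)
  data.table::fwrite(rk, file.path(dir, "ranks.tsv.gz"), sep = "\t",
                     compress = "gzip")
  data.table::fwrite(db$meta, file.path(dir, "instances.tsv"), sep = "\t")
  invisible(dir)
}

#' Load a reference database saved by [save_refdb()]
#'
#' @param dir database directory.
#' @return A `ref_db`.
#' @export
load_refdb <- function(dir) {
  probes <- readLines(file.path(dir, "probes.txt"))
  con <- gzfile(file.path(dir, "ranks.tsv.gz"), "rt")
  on.exit(close(con))
  rk <- utils::read.table(con, header = TRUE, sep = "\t",
                          colClasses = c("character",
                                         rep("integer", length(probes))),
                          check.names = FALSE)
  meta <- as.data.frame(data.table::fread(file.path(dir, "instances.tsv"),
                                          sep = "\t", colClasses = "character"))
  ids <- rk[[1L]]
  ranks <- as.matrix(rk[, -1L, drop = FALSE])
  storage.mode(ranks) <- "integer"
  dimnames(ranks) <- list(ids, probes)
  db <- structure(list(probe_ids = probes, ranks = ranks,
                       meta = meta[match(ids, meta$instance_id), , drop = FALSE]),
                  class = "ref_db")
  validate_refdb(db)
  db
}

# check the signed-permutation invariant for every stored profile
validate_refdb <- function(db) {
  n <- length(db$probe_ids)
  for (i in seq_len(nrow(db$ranks))) {
    a <- sort(abs(db$ranks[i, ]))
    if (!identical(as.integer(a), seq_len(n)))
      stop("profile '", rownames(db$ranks)[i],
           "' is not a signed permutation of 1..", n)
  }
  invisible(db)
}

#' Read an expression matrix from TSV
#'
#' Expected layout: first column `probe_id`, remaining columns one per
#' instance (header = instance ids), tab-separated.
#'
#' @param path file path.
#' @return Numeric matrix probes x instances with dimnames.
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  if (ncol(dt) < 2L) stop("malformed expression TSV '", path,
                          "': need probe_id plus at least one instance column")
  probe_ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L])
  if (!is.numeric(m)) stop("malformed expression TSV '", path,
                           "': non-numeric expression values")
  rownames(m) <- probe_ids
  m
}

#' Read an instance-metadata table from TSV
#'
#' @param path file path; must contain the columns `instance_id`,
#'   `perturbagen`, `cell_line`, `dose`, `time`, `plate_id`, `is_control`.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  meta <- as.data.frame(data.table::fread(path, sep = "\t"))
  required <- c("instance_id", "perturbagen", "cell_line", "dose", "time",
                "plate_id", "is_control")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("malformed metadata TSV '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (cl in setdiff(required, "is_control")) meta[[cl]] <- as.character(meta[[cl]])
  meta
}
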