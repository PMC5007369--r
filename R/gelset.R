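#' @keywords internal
"_PACKAGE"

.GROUPS <- c("NH", "HF")
.CHANNELS <- c("Asc+", "Asc-")

#' Construct a gel set
#'
#' A `gelset` couples a spot-volume matrix (spots x gels) with per-gel
#' annotations: subject id, group (`NH` healthy control or `HF` heart
#' failure) and channel (`Asc+` ascorbate-reduced, measuring total protein
#' thiols, or `Asc-` neocuproine-stabilized, in which S-nitrosylated
#' cysteines do not bind the dye).  Volumes are non-negative fluorescence
#' spot volumes; zeros mark undetected spots.
#'
#' @param volumes numeric matrix, rows = spots (rownames are spot ids),
#'   columns = gels (colnames are gel ids), all values `>= 0`.
#' @param gel_meta data.frame with columns `gel_id`, `subject_id`, `group`,
#'   `channel`, one row per column of `volumes`.
#' @param normalized logical flag, `TRUE` after bias-factor normalization.
#' @param reference_gel gel id of the normalization reference, or `NA`.
#' @return an object of class `gelset`.
#' @seealso [read_gelset()], [normalize_gelset()], [simulate_gelset()]
#' @export
gelset <- function(volumes, gel_meta, normalized = FALSE, reference_gel = NA_character_) {
  volumes <- as.matrix(volumes)
  storage.mode(volumes) <- "double"
  gel_meta <- as.data.frame(gel_meta, stringsAsFactors = FALSE)
  obj <- structure(
    list(volumes = volumes, gel_meta = gel_meta,
         normalized = isTRUE(normalized),
         reference_gel = as.character(reference_gel)),
    class = "gelset")
  validate_gelset(obj)
}

#' @rdname gelset
#' @param x a `gelset`.
#' @export
validate_gelset <- function(x) {
  stopifnot(inherits(x, "gelset"))
  v <- x$volumes
  m <- x$gel_meta
  need <- c("gel_id", "subject_id", "group", "channel")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop("gel_meta is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    stop("volumes must carry spot ids as rownames and gel ids as colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(v))) stop("duplicate spot ids in volumes", call. = FALSE)
  if (anyDuplicated(colnames(v))) stop("duplicate gel ids in volumes", call. = FALSE)
  if (anyDuplicated(m$gel_id)) stop("duplicate gel ids in gel_meta", call. = FALSE)
  extra <- setdiff(colnames(v), m$gel_id)
  if (length(extra)) {
    stop("gel '", extra[1L], "' in volumes has no metadata row", call. = FALSE)
  }
  extra <- setdiff(m$gel_id, colnames(v))
  if (length(extra)) {
    stop("gel '", extra[1L], "' in gel_meta is absent from volumes", call. = FALSE)
  }
  bad <- setdiff(unique(m$group), .GROUPS)
  if (length(bad)) {
    stop("unknown group token '", bad[1L], "' (expected ",
         paste(.GROUPS, collapse = ", "), ")", call. = FALSE)
  }
  bad <- setdiff(unique(m$channel), .CHANNELS)
  if (length(bad)) {
    stop("unknown channel token '", bad[1L], "' (expected ",
         paste(.CHANNELS, collapse = ", "), ")", call. = FALSE)
  }
  if (anyNA(v) || any(!is.finite(v))) {
    idx <- which(!is.finite(v) | is.na(v), arr.ind = TRUE)[1L, ]
    stop("non-finite volume at spot '", rownames(v)[idx[1L]], "', gel '",
         colnames(v)[idx[2L]], "'", call. = FALSE)
  }
  if (any(v < 0)) {
    idx <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop("negative volume at spot '", rownames(v)[idx[1L]], "', gel '",
         colnames(v)[idx[2L]], "'", call. = FALSE)
  }
  # align metadata row order to the volume columns
  x$gel_meta <- m[match(colnames(v), m$gel_id), , drop = FALSE]
  rownames(x$gel_meta) <- NULL
  x
}

#' @export
print.gelset <- function(x, ...) {
  m <- x$gel_meta
  cat(sprintf("gelset: %d spots x %d gels (%s)\n",
              nrow(x$volumes), ncol(x$volumes),
              if (x$normalized) paste0("normalized, reference ", x$reference_gel)
              else "raw"))
  tab <- table(group = m$group, channel = m$channel)
  print(tab)
  invisible(x)
}

#' Subset the gels of a gel set
#'
#' @param x a `gelset`.
#' @param gel_ids gel ids to keep.
#' @return a `gelset` restricted to the requested gels.
#' @export
subset_gels <- function(x, gel_ids) {
  stopifnot(inherits(x, "gelset"))
  missing_ids <- setdiff(gel_ids, colnames(x$volumes))
  if (length(missing_ids)) {
    stop("unknown gel id '", missing_ids[1L], "'", call. = FALSE)
  }
  gelset(x$volumes[, gel_ids, drop = FALSE],
         x$gel_meta[match(gel_ids, x$gel_meta$gel_id), , drop = FALSE],
         normalized = x$normalized, reference_gel = x$reference_gel)
}

# gel ids for one group/channel cell
.gels_for <- function(x, group = NULL, channel = NULL) {
  m <- x$gel_meta
  keep <- rep(TRUE, nrow(m))
  if (!is.null(group)) keep <- keep & m$group == group
  if (!is.null(channel)) keep <- keep & m$channel == channel
  m$gel_id[keep]
}

#' Read and write gel sets as TSV pairs
#'
#' The canonical on-disk form is a pair of UTF-8 tab-separated files: a
#' volumes table whose first column `spot_id` is followed by one numeric
#' column per gel, and a metadata table with columns `gel_id`,
#' `subject_id`, `group`, `channel`.
#'
#' @param volumes_path path to the volumes TSV.
#' @param meta_path path to the gel-metadata TSV.
#' @return `read_gelset()` returns a validated `gelset`.
#' @export
read_gelset <- function(volumes_path, meta_path) {
  for (p in c(volumes_path, meta_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  vol <- utils::read.delim(volumes_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(vol)[1L] != "spot_id") {
    stop("volumes file must have 'spot_id' as its first column (", volumes_path, ")",
         call. = FALSE)
  }
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  spot_ids <- as.character(vol$spot_id)
  mat <- as.matrix(vol[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(vol[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric volume column '", names(vol)[-1L][bad], "' in ", volumes_path,
         call. = FALSE)
  }
  rownames(mat) <- spot_ids
  gelset(mat, meta)
}

#' @rdname read_gelset
#' @param x a `gelset` to write.
#' @export
write_gelset <- function(x, volumes_path, meta_path) {
  stopifnot(inherits(x, "gelset"))
  df <- data.frame(spot_id = rownames(x$volumes), x$volumes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, volumes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$gel_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(volumes = volumes_path, meta = meta_path))
}
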