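#' Copy-number matrix
#'
#' Container for integer copy-number profiles of all samples over a shared
#' set of genomic sites (bins or segments). For total input only the total
#' matrix is stored; for haplotype-specific input the per-haplotype matrices
#' \code{A} and \code{B} are stored alongside their total.
#'
#' @param values n x m integer matrix of total copy numbers (samples x
#'   sites); ignored (derived) when \code{A}/\code{B} are given.
#' @param sites Data frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive bp), one row per site.
#' @param sample_ids Character vector of n sample labels.
#' @param kind \code{"total"} or \code{"haplotype"}.
#' @param A,B Haplotype copy-number matrices (required for
#'   \code{kind = "haplotype"}).
#' @return An object of class \code{cn_matrix}.
#' @export
cn_matrix <- function(values = NULL, sites, sample_ids, kind = "total",
                      A = NULL, B = NULL) {
  kind <- match.arg(kind, c("total", "haplotype"))
  if (kind == "haplotype") {
    stopifnot(!is.null(A), !is.null(B), all(dim(A) == dim(B)))
    if (any(A < 0) || any(B < 0)) {
      stop("haplotype copy numbers must be non-negative", call. = FALSE)
    }
    values <- A + B
  }
  stopifnot(is.matrix(values))
  if (any(!is.finite(values)) || any(values != round(values))) {
    stop("copy numbers must be integers with no missing entries",
         call. = FALSE)
  }
  if (nrow(sites) != ncol(values)) {
    stop("`sites` must have one row per column of `values`", call. = FALSE)
  }
  if (length(sample_ids) != nrow(values)) {
    stop("`sample_ids` must have one entry per row of `values`",
         call. = FALSE)
  }
  rownames(values) <- sample_ids
  if (!is.null(A)) { rownames(A) <- sample_ids; rownames(B) <- sample_ids }
  structure(list(values = values, A = A, B = B,
                 sites = as.data.frame(sites), sample_ids = sample_ids,
                 kind = kind),
            class = "cn_matrix")
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix: %d samples x %d sites (%s copy numbers)\n",
              nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' Read a copy-number table
#'
#' Reads the package's TSV dialect: a header line then one row per sample
#' and site with columns \code{sample_id}, \code{chrom}, \code{start},
#' \code{end} and either \code{cn} (total input) or \code{cnA}, \code{cnB}
#' (haplotype-specific input). Every sample must cover the identical sites
#' in identical order.
#'
#' @param path Path to the TSV file.
#' @param kind \code{"total"} or \code{"haplotype"}.
#' @return A \code{cn_matrix}.
#' @export
read_cn_table <- function(path, kind = c("total", "haplotype")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "chrom", "start", "end",
            if (kind == "total") "cn" else c("cnA", "cnB"))
  if (!all(need %in% names(tab))) {
    stop("copy-number table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  samples <- unique(tab$sample_id)
  key <- paste(tab$chrom, tab$start, tab$end, sep = ":")
  if (anyDuplicated(paste(tab$sample_id, key))) {
    stop("duplicate (sample, site) rows in copy-number table",
         call. = FALSE)
  }
  first <- key[tab$sample_id == samples[1L]]
  rows <- lapply(samples, function(s) {
    sub <- tab[tab$sample_id == s, , drop = FALSE]
    if (!identical(paste(sub$chrom, sub$start, sub$end, sep = ":"), first)) {
      stop("sample '", s, "' does not cover the same sites in the same ",
           "order as sample '", samples[1L], "'", call. = FALSE)
    }
    sub
  })
  sites <- rows[[1L]][, c("chrom", "start", "end")]
  rownames(sites) <- NULL
  if (kind == "total") {
    vals <- do.call(rbind, lapply(rows, function(r) r$cn))
    cn_matrix(vals, sites, samples, kind = "total")
  } else {
    A <- do.call(rbind, lapply(rows, function(r) r$cnA))
    B <- do.call(rbind, lapply(rows, function(r) r$cnB))
    cn_matrix(sites = sites, sample_ids = samples, kind = "haplotype",
              A = A, B = B)
  }
}

#' Write a copy-number matrix in the package's TSV dialect
#'
#' @param x A \code{cn_matrix}.
#' @param path Output path.
#' @export
write_cn_table <- function(x, path) {
  stopifnot(inherits(x, "cn_matrix"))
  base <- data.frame(
    sample_id = rep(x$sample_ids, each = ncol(x$values)),
    chrom = rep(x$sites$chrom, nrow(x$values)),
    start = rep(x$sites$start, nrow(x$values)),
    end = rep(x$sites$end, nrow(x$values))
  )
  if (x$kind == "total") {
    base$cn <- as.vector(t(x$values))
  } else {
    base$cnA <- as.vector(t(x$A))
    base$cnB <- as.vector(t(x$B))
  }
  utils::write.table(base, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Shift relative copy numbers to absolute values
#'
#' Relative total copy numbers as reported by sWGS callers take values in
#' \{-2, ..., 2\} (double deletion to amplification relative to normal
#' ploidy). Adding the normal ploidy 2 maps them onto absolute totals in
#' \{0, ..., 4\}.
#'
#' @param x A \code{cn_matrix} of kind \code{"total"} with values in
#'   \code{[-2, 2]}.
#' @return A \code{cn_matrix} with all values shifted by +2.
#' @export
absolutize_relative <- function(x) {
  stopifnot(inherits(x, "cn_matrix"))
  if (x$kind != "total") {
    stop("relative input is only supported for total copy numbers",
         call. = FALSE)
  }
  if (any(x$values < -2) || any(x$values > 2)) {
    stop("relative copy numbers must lie in [-2, 2]", call. = FALSE)
  }
  cn_matrix(x$values + 2L, x$sites, x$sample_ids, kind = "total")
}

#' Merge consecutive bins with identical copy-number columns into segments
#'
#' Maximal runs of consecutive bins on one chromosome whose copy-number
#' column vector (over all samples, and over both haplotypes for
#' haplotype-specific input) is identical collapse to a single segment
#' spanning them. The operation is idempotent and lossless for the
#' likelihood, which only depends on site patterns and their counts.
#'
#' @param x A \code{cn_matrix} at bin level, bins sorted by chromosome then
#'   start position.
#' @return A \code{cn_matrix} at segment level.
#' @export
merge_segments <- function(x) {
  stopifnot(inherits(x, "cn_matrix"))
  s <- x$sites
  for (chr in unique(s$chrom)) {
    st <- s$start[s$chrom == chr]
    if (is.unsorted(st)) {
      stop("bins on chromosome ", chr, " are not sorted by start position",
           call. = FALSE)
    }
  }
  colkey <- apply(x$values, 2L, paste, collapse = ",")
  if (x$kind == "haplotype") {
    colkey <- paste(apply(x$A, 2L, paste, collapse = ","),
                    apply(x$B, 2L, paste, collapse = ","), sep = ";")
  }
  grp <- cumsum(c(TRUE, colkey[-1L] != colkey[-length(colkey)] |
                    s$chrom[-1L] != s$chrom[-nrow(s)]))
  keep <- !duplicated(grp)
  sites <- data.frame(
    chrom = s$chrom[keep],
    start = s$start[keep],
    end = tapply(s$end, grp, function(z) z[length(z)])[as.character(unique(grp))]
  )
  rownames(sites) <- NULL
  if (x$kind == "total") {
    cn_matrix(x$values[, keep, drop = FALSE], sites, x$sample_ids, "total")
  } else {
    cn_matrix(sites = sites, sample_ids = x$sample_ids, kind = "haplotype",
              A = x$A[, keep, drop = FALSE], B = x$B[, keep, drop = FALSE])
  }
}

#' Sampling-time metadata
#'
#' @param times Named numeric vector of per-sample times in years; shifted
#'   so the first (earliest) sample is at 0.
#' @param A0 Patient age in years at the first sampling time.
#' @return An object of class \code{sample_timing} with fields
#'   \code{times} (offsets in years, min 0), \code{A0}, and \code{d}
#'   (largest offset).
#' @export
sample_timing <- function(times, A0) {
  if (is.null(names(times)) || any(names(times) == "")) {
    stop("`times` must be named by sample id", call. = FALSE)
  }
  if (!is.finite(A0) || A0 <= 0) stop("`A0` must be positive", call. = FALSE)
  offs <- times - min(times)
  structure(list(times = offs, A0 = A0, d = max(offs)),
            class = "sample_timing")
}

#' Read sampling times
#'
#' The timing file is a TSV with columns \code{sample_id} and \code{time},
#' preceded by comment header lines \code{# unit=days|years} and
#' \code{# patient_age_first_sample=<years>}. Times in days are converted
#' to years by dividing by 365; the first sample is set to time 0.
#'
#' @param path Path to the timing TSV.
#' @param samples Optional character vector of sample ids that must all be
#'   present (consistency check against a copy-number matrix).
#' @return A \code{sample_timing}.
#' @export
read_timing <- function(path, samples = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  unit <- if ("unit" %in% keys) trimws(vals[match("unit", keys)]) else "years"
  if (!unit %in% c("days", "years")) {
    stop("timing header `unit` must be 'days' or 'years'", call. = FALSE)
  }
  A0 <- if ("patient_age_first_sample" %in% keys) {
    as.numeric(vals[match("patient_age_first_sample", keys)])
  } else NA_real_
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "time") %in% names(tab))) {
    stop("timing file must have columns sample_id and time", call. = FALSE)
  }
  tm <- tab$time
  if (unit == "days") tm <- tm / 365
  names(tm) <- tab$sample_id
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(tm))
    if (length(missing) > 0) {
      stop("samples missing from timing file: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    tm <- tm[samples]
  }
  sample_timing(tm, A0)
}

#' Write sampling times
#'
#' @param timing A \code{sample_timing}.
#' @param path Output path.
#' @export
write_timing <- function(timing, path) {
  stopifnot(inherits(timing, "sample_timing"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# unit=years",
               sprintf("# patient_age_first_sample=%.10g", timing$A0),
               "sample_id\ttime"), con)
  writeLines(sprintf("%s\t%.10g", names(timing$times), timing$times), con)
  invisible(path)
}
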