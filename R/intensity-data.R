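#' Construct an intensity dataset
#'
#' An `intensity_dataset` holds per-(SNP, sample) two-channel raw
#' fluorescence intensities \eqn{x_{is} = (r_{is}, g_{is})}, where `r` is the
#' allele-A channel and `g` the allele-B channel. SNP order is significant:
#' reference-SNP search for hard-to-call SNPs scans SNPs *before* the target
#' in dataset (array) order. Missing (SNP, sample) cells are simply absent
#' rows; they are tracked and always reported as no-calls downstream.
#'
#' @param data data.frame with columns `snp`, `sample`, `r`, `g` (long form,
#'   one row per observed cell). Intensities must be finite and non-negative.
#' @param populations optional named character vector mapping sample id to a
#'   population label (used only by [hwe_test()]).
#' @param snp_order optional character vector fixing SNP order; defaults to
#'   first-appearance order in `data`.
#' @return An object of class `intensity_dataset` with elements `data`
#'   (validated long-form data.frame), `snp_ids`, `sample_ids`,
#'   `populations`, and `snp_index` (row indices per SNP).
#' @seealso [read_intensities()], [simulate_panel()]
#' @export
intensity_dataset <- function(data, populations = NULL, snp_order = NULL) {
  req <- c("snp", "sample", "r", "g")
  if (!is.data.frame(data) || !all(req %in% names(data)))
    stop("`data` must be a data.frame with columns snp, sample, r, g")
  data$snp <- as.character(data$snp)
  data$sample <- as.character(data$sample)
  data$r <- as.numeric(data$r)
  data$g <- as.numeric(data$g)
  bad <- !is.finite(data$r) | !is.finite(data$g)
  if (any(bad))
    stop("non-finite intensity at row(s): ", paste(utils::head(which(bad), 5L), collapse = ", "))
  neg <- data$r < 0 | data$g < 0
  if (any(neg))
    stop("negative intensity at row(s): ", paste(utils::head(which(neg), 5L), collapse = ", "))
  key <- paste(data$snp, data$sample, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (SNP, sample) cell(s): ",
         paste(utils::head(unique(sub("\r", "/", key[duplicated(key)])), 5L), collapse = ", "))
  snp_ids <- if (is.null(snp_order)) unique(data$snp) else as.character(snp_order)
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids in snp_order")
  if (!all(data$snp %in% snp_ids)) stop("snp_order does not cover all SNPs in data")
  sample_ids <- unique(data$sample)
  if (!is.null(populations)) {
    populations <- as.character(populations)[match(sample_ids, names(populations))]
    names(populations) <- sample_ids
    if (anyNA(populations))
      warning("population label missing for some samples; they are excluded from HWE tests")
  }
  snp_index <- split(seq_len(nrow(data)), factor(data$snp, levels = snp_ids))
  structure(
    list(data = data, snp_ids = snp_ids, sample_ids = sample_ids,
         populations = populations, snp_index = snp_index),
    class = "intensity_dataset"
  )
}

#' @export
print.intensity_dataset <- function(x, ...) {
  n_cells <- nrow(x$data)
  cat("Two-channel SNP intensity dataset\n")
  cat(sprintf("  %d SNPs x %d samples (%d observed cells, %d missing)\n",
              length(x$snp_ids), length(x$sample_ids), n_cells,
              length(x$snp_ids) * length(x$sample_ids) - n_cells))
  if (!is.null(x$populations))
    cat("  populations:", paste(names(table(x$populations)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of observed samples per SNP
#'
#' @param ds an [intensity_dataset()]
#' @return named integer vector, \eqn{n_s} per SNP in dataset order.
#' @export
n_obs <- function(ds) {
  stopifnot(inherits(ds, "intensity_dataset"))
  out <- vapply(ds$snp_index, length, integer(1L))
  names(out) <- ds$snp_ids
  out
}

#' Extract one SNP's intensity matrix
#'
#' @param ds an [intensity_dataset()]
#' @param snp SNP identifier
#' @return numeric matrix with columns `r`, `g` and sample ids as rownames.
#' @export
snp_intensities <- function(ds, snp) {
  stopifnot(inherits(ds, "intensity_dataset"))
  idx <- ds$snp_index[[snp]]
  if (is.null(idx)) stop("unknown SNP: ", snp)
  m <- cbind(r = ds$data$r[idx], g = ds$data$g[idx])
  rownames(m) <- ds$data$sample[idx]
  m
}

#' Contrast projection of a two-channel intensity pair
#'
#' Projects the intensity pair onto the univariate contrast
#' \eqn{y = (r - g) / (r + g)}, which separates the three genotype clusters
#' along one axis (homozygous AA near +1, heterozygous near 0, homozygous BB
#' near -1). Antisymmetric under swapping the channels.
#'
#' @param r,g non-negative channel intensities (vectorized).
#' @return contrast values in \eqn{[-1, 1]}.
#' @export
compute_contrast <- function(r, g) {
  if (any(r < 0 | g < 0, na.rm = TRUE)) stop("negative intensity")
  s <- r + g
  if (any(s == 0, na.rm = TRUE))
    stop("degenerate intensity pair: r + g = 0 (treat as missing)")
  (r - g) / s
}

## Contrast with NA (not error) for degenerate pairs; internal helper used
## where degenerate points must be dropped rather than abort a fit.
contrast_or_na <- function(r, g) {
  s <- r + g
  ifelse(s > 0, (r - g) / s, NA_real_)
}

#' Read a long-form intensity TSV
#'
#' Expects a tab-delimited UTF-8 file with a mandatory header containing
#' columns `SNP`, `Sample`, `r`, `g` and optionally `Population`. SNP order
#' in the returned dataset equals first-appearance order in the file.
#'
#' @param path file path.
#' @return an [intensity_dataset()].
#' @export
read_intensities <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("SNP", "Sample", "r", "g")
  if (!all(req %in% names(df)))
    stop("intensity file must have header columns SNP, Sample, r, g; got: ",
         paste(names(df), collapse = ", "))
  for (cc in c("r", "g")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad))
      stop(sprintf("malformed %s value at data line %d of %s", cc, bad[1L], path))
    df[[cc]] <- v
  }
  pops <- NULL
  if ("Population" %in% names(df)) {
    pops <- tapply(as.character(df$Population), df$Sample, function(v) v[1L])
    pops <- stats::setNames(as.character(pops), names(pops))
  }
  intensity_dataset(
    data.frame(snp = df$SNP, sample = df$Sample, r = df$r, g = df$g,
               stringsAsFactors = FALSE),
    populations = pops
  )
}

#' Write per-call genotype table
#'
#' Writes calls as TSV with columns `SNP`, `Sample`, `Genotype`, `PR`,
#' `Model`; no-calls carry the literal genotype token `NC`. Posterior rates
#' are serialized at full precision so the file round-trips losslessly
#' through [read_calls()].
#'
#' @param calls a call table (data.frame with columns `snp`, `sample`,
#'   `genotype`, `pr`, `model`) or an object with a `$calls` element such as
#'   the result of [run_md()].
#' @param path output file path.
#' @export
write_calls <- function(calls, path) {
  calls <- as_call_table(calls)
  if (nrow(calls) == 0L) stop("empty call set")
  out <- data.frame(SNP = calls$snp, Sample = calls$sample,
                    Genotype = calls$genotype,
                    PR = formatC(calls$pr, format = "g", digits = 15),
                    Model = calls$model, stringsAsFactors = FALSE)
  out$PR[is.na(calls$pr)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype call table written by [write_calls()]
#'
#' @param path file path.
#' @return data.frame with columns `snp`, `sample`, `genotype`, `pr`,
#'   `model`.
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("SNP", "Sample", "Genotype", "PR", "Model")
  if (!all(req %in% names(df)))
    stop("call file must have columns SNP, Sample, Genotype, PR, Model")
  ok <- c("AA", "AB", "BB", "NC")
  if (!all(df$Genotype %in% ok))
    stop("invalid genotype token(s): ",
         paste(utils::head(setdiff(df$Genotype, ok), 5L), collapse = ", "))
  data.frame(snp = df$SNP, sample = df$Sample, genotype = df$Genotype,
             pr = suppressWarnings(as.numeric(df$PR)), model = df$Model,
             stringsAsFactors = FALSE)
}

#' Write per-SNP summary table
#'
#' One row per SNP: average posterior rate, minor allele frequency, routing
#' group, model used, and per-genotype cluster sizes. A SNP with no called
#' samples reports MAF as the missing token `NA`.
#'
#' @param fit an object with a `$snp_summary` data.frame (e.g. [run_md()]
#'   output) or the summary data.frame itself.
#' @param path output file path.
#' @export
write_snp_summary <- function(fit, path) {
  s <- if (is.data.frame(fit)) fit else fit$snp_summary
  if (is.null(s) || nrow(s) == 0L) stop("empty SNP summary")
  out <- data.frame(SNP = s$snp,
                    APR = formatC(s$apr, format = "g", digits = 15),
                    MAF = formatC(s$maf, format = "g", digits = 15),
                    Group = s$group, Model = s$model,
                    n_AA = s$n_AA, n_AB = s$n_AB, n_BB = s$n_BB, n_NC = s$n_NC,
                    stringsAsFactors = FALSE)
  out$MAF[is.na(s$maf)] <- "NA"
  out$APR[is.na(s$apr)] <- "NA"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-SNP summary table written by [write_snp_summary()]
#'
#' @param path file path.
#' @return data.frame with columns `snp`, `apr`, `maf`, `group`, `model`,
#'   `n_AA`, `n_AB`, `n_BB`, `n_NC`.
#' @export
read_snp_summary <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(snp = df$SNP, apr = suppressWarnings(as.numeric(df$APR)),
             maf = suppressWarnings(as.numeric(df$MAF)),
             group = df$Group, model = df$Model,
             n_AA = df$n_AA, n_AB = df$n_AB, n_BB = df$n_BB, n_NC = df$n_NC,
             stringsAsFactors = FALSE)
}

## Coerce run_md() results / plain data.frames into the canonical call table.
as_call_table <- function(x) {
  if (is.data.frame(x)) {
    calls <- x
  } else if (!is.null(x$calls)) {
    calls <- x$calls
  } else {
    stop("cannot interpret object as a call table")
  }
  req <- c("snp", "sample", "genotype", "pr")
  if (!all(req %in% names(calls)))
    stop("call table needs columns snp, sample, genotype, pr")
  if (is.null(calls$model)) calls$model <- NA_character_
  calls
}
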