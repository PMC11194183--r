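#' log(x + 1) transform of an expression matrix
#'
#' Applies `v -> log(1 + v)` elementwise (natural log by default; the
#' downstream Pearson correlation is invariant to the base).
#'
#' @param values non-negative numeric matrix, genes x samples.
#' @param base logarithm base.
#' @return Transformed matrix of the same shape.
#' @export
log_transform <- function(values, base = exp(1)) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)
  log1p(values) / log(base)
}

#' Correlate gene expression with aragonite saturation state
#'
#' Pearson correlation, per gene, of log(x + 1)-transformed expression
#' against the saturation state of each sample, with the biomarker-screen
#' pass filters `|r| > 0.5` and `r^2 > 0.4`. Genes with zero expression
#' variance have undefined r; they are flagged `constant` and never pass.
#'
#' @param values non-negative numeric matrix, genes x samples (raw TMM
#'   abundances; set `log = FALSE` if already transformed).
#' @param omega_ar numeric vector of per-sample saturation states
#'   (>= 3 distinct values required).
#' @param log apply [log_transform()] first (default TRUE).
#' @return A data.frame of class `"screen_result"` with columns `gene`,
#'   `r`, `r2`, `passes_r`, `passes_r2`, `constant`.
#' @export
correlate_with_omega <- function(values, omega_ar, log = TRUE) {
  values <- as.matrix(values)
  if (ncol(values) != length(omega_ar))
    stop("omega_ar must have one value per sample (column)", call. = FALSE)
  if (length(unique(omega_ar)) < 3)
    stop("need >= 3 distinct omega_ar values across samples", call. = FALSE)
  if (log) values <- log_transform(values)
  constant <- if (nrow(values)) apply(values, 1, stats::sd) == 0 else
    logical(0)
  r <- rep(NA_real_, nrow(values))
  if (any(!constant))
    r[!constant] <- as.numeric(
      stats::cor(t(values[!constant, , drop = FALSE]), omega_ar))
  out <- data.frame(
    gene = if (!is.null(rownames(values))) rownames(values) else
      sprintf("g%d", seq_len(nrow(values))),
    r = r, r2 = r^2,
    passes_r = !is.na(r) & abs(r) > 0.5,
    passes_r2 = !is.na(r) & r^2 > 0.4,
    constant = constant)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Count genes passing the biomarker-screen filters
#'
#' @param result a [correlate_with_omega()] result.
#' @return Named integer vector `c(n_abs_r, n_r2)`: genes with
#'   `|r| > 0.5` and with `r^2 > 0.4`. Always `n_r2 <= n_abs_r` since
#'   `r^2 > 0.4` implies `|r| > 0.632`.
#' @export
count_passing <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  c(n_abs_r = sum(result$passes_r), n_r2 = sum(result$passes_r2))
}

#' Screen an expression matrix against sample saturation states
#'
#' Convenience wrapper joining a genes x samples matrix with per-sample
#' metadata (by column name / `sample_id`) and running
#' [correlate_with_omega()].
#'
#' @param values genes x samples matrix with sample IDs as column names.
#' @param meta data.frame with columns `sample_id` and `omega_ar`.
#' @param ... passed to [correlate_with_omega()].
#' @return A `"screen_result"` data.frame.
#' @export
biomarker_screen <- function(values, meta, ...) {
  stopifnot(is.data.frame(meta), all(c("sample_id", "omega_ar") %in%
                                       names(meta)))
  idx <- match(colnames(values), meta$sample_id)
  if (any(is.na(idx)))
    stop("metadata is missing samples: ",
         paste(colnames(values)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  correlate_with_omega(values, meta$omega_ar[idx], ...)
}
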