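#' Neutrality regression of GC12 on GC3
#'
#' Unweighted ordinary least squares of per-gene GC12 (mean GC of the first
#' two codon positions) on GC3. A slope near 1 with a strong correlation
#' indicates mutation pressure as the dominant force; a slope near 0
#' indicates selection. The mutation share is reported as |slope| * 100%
#' and the selection share as its complement; a negative fitted slope is
#' flagged since the share heuristic then rests on the absolute value.
#'
#' @param gc12,gc3 Per-gene GC fractions (>= 3 genes).
#' @return A list of class `"neutrality_fit"`: `slope`, `intercept`,
#'   `pearson_r`, `p_value`, `mutation_share`, `selection_share` (percent),
#'   `slope_negative`, `n`.
#' @export
neutrality_fit <- function(gc12, gc3) {
  keep <- stats::complete.cases(gc12, gc3)
  gc12 <- gc12[keep]; gc3 <- gc3[keep]
  stopifnot(length(gc3) >= 3)
  if (stats::var(gc3) == 0) stop("GC3 has zero variance; regression undefined")
  fit <- stats::lm(gc12 ~ gc3)
  ct <- if (stats::var(gc12) > 0) stats::cor.test(gc3, gc12) else
    list(estimate = NA_real_, p.value = NA_real_)
  slope <- unname(stats::coef(fit)[2])
  out <- list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    mutation_share = 100 * abs(slope),
    selection_share = 100 * (1 - abs(slope)),
    slope_negative = slope < 0,
    n = length(gc3)
  )
  class(out) <- "neutrality_fit"
  out
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality fit (n = %d): GC12 = %.4f + %.4f * GC3 (r = %.3f, p = %.3g)\n",
    x$n, x$intercept, x$slope, x$pearson_r, x$p_value))
  cat(sprintf("  mutation share %.1f%%, selection share %.1f%%%s\n",
              x$mutation_share, x$selection_share,
              if (x$slope_negative) " [negative slope: shares use |slope|]" else ""))
  invisible(x)
}

#' Correspondence analysis of a per-gene codon usage matrix
#'
#' Standard correspondence analysis: with P the matrix of relative
#' frequencies, r and c its margins, the standardized residuals
#' S = D_r^(-1/2) (P - r c') D_c^(-1/2) are decomposed by SVD. Row (gene)
#' and column (codon) principal coordinates and the inertia share of each
#' axis (squared singular value over total inertia) are returned. The usual
#' input is the genes x 59 per-gene RSCU matrix from [rscu_matrix()]
#' (raw counts can be passed instead for the count-based variant).
#'
#' All-zero rows or columns are dropped with a warning; `NA` cells (genes
#' with an unused amino-acid family) are treated as zero usage.
#'
#' @param mat Non-negative matrix, genes in rows.
#' @param n_axes Number of axes to keep (default: all with positive inertia).
#' @return A list of class `"coa_result"`: `row_coords`, `col_coords`
#'   (principal coordinates), `inertia` (per axis), `percent_inertia`,
#'   `total_inertia`.
#' @export
correspondence_analysis <- function(mat, n_axes = NULL) {
  mat <- as.matrix(mat)
  mat[is.na(mat)] <- 0
  if (any(mat < 0)) stop("correspondence analysis needs a non-negative matrix")
  keep_r <- rowSums(mat) > 0
  keep_c <- colSums(mat) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning(sum(!keep_r), " all-zero row(s) and ", sum(!keep_c),
            " all-zero column(s) dropped")
    mat <- mat[keep_r, keep_c, drop = FALSE]
  }
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  p <- mat / sum(mat)
  r <- rowSums(p); c <- colSums(p)
  s <- (p - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(s)
  tol <- max(dim(mat)) * .Machine$double.eps * sv$d[1]
  pos <- which(sv$d > max(tol, 0))
  k_max <- min(length(pos), min(dim(mat)) - 1L)
  pos <- pos[seq_len(k_max)]
  total <- sum(sv$d[pos]^2)
  if (length(pos) == 0 || total == 0) {
    out <- list(row_coords = matrix(0, nrow(mat), 0), col_coords = matrix(0, ncol(mat), 0),
                inertia = numeric(0), percent_inertia = numeric(0), total_inertia = 0)
    class(out) <- "coa_result"
    return(out)
  }
  k <- if (is.null(n_axes)) length(pos) else min(n_axes, length(pos))
  d <- sv$d[pos]
  row_coords <- sweep(sv$u[, pos, drop = FALSE], 1, sqrt(r), "/") %*% diag(d, length(pos))
  col_coords <- sweep(sv$v[, pos, drop = FALSE], 1, sqrt(c), "/") %*% diag(d, length(pos))
  dimnames(row_coords) <- list(rownames(mat), paste0("axis", seq_along(pos)))
  dimnames(col_coords) <- list(colnames(mat), paste0("axis", seq_along(pos)))
  out <- list(
    row_coords = row_coords[, seq_len(k), drop = FALSE],
    col_coords = col_coords[, seq_len(k), drop = FALSE],
    inertia = d[seq_len(k)]^2,
    percent_inertia = 100 * d[seq_len(k)]^2 / total,
    total_inertia = total
  )
  attr(out, "all_inertia") <- d^2
  class(out) <- "coa_result"
  out
}

#' @export
print.coa_result <- function(x, ...) {
  cat("Correspondence analysis:", nrow(x$row_coords), "rows,",
      nrow(x$col_coords), "columns, total inertia",
      signif(x$total_inertia, 4), "\n")
  if (length(x$percent_inertia)) {
    cat("  axis inertia (%):",
        paste(sprintf("%.2f", utils::head(x$percent_inertia, 6)), collapse = ", "),
        if (length(x$percent_inertia) > 6) "...", "\n")
  }
  invisible(x)
}
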