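# Performance measures: regression metrics, stabilizing/destabilizing
# classification, direct/inverse anti-symmetry bias, and SNV stratification.

#' Regression metrics
#'
#' @param pred,exp Equal-length numeric vectors (kcal/mol).
#' @return List with `pcc`, `rmse`, `mae`.
#' @export
regression_metrics <- function(pred, exp) {
  if (length(pred) != length(exp) || length(pred) < 2) {
    stop("need two equal-length vectors of length >= 2")
  }
  if (stats::sd(exp) == 0) stop("PCC undefined: experimental values are constant")
  # constant predictions give an NA correlation without a warning
  list(pcc = suppressWarnings(stats::cor(pred, exp)),
       rmse = sqrt(mean((pred - exp)^2)),
       mae = mean(abs(pred - exp)))
}

#' Classification metrics for stabilizing vs destabilizing mutations
#'
#' A mutation is stabilizing when its ddG is strictly below the threshold
#' (default 0; ddG = 0 counts as destabilizing). Stabilizing is the
#' positive class. MCC is 0 when a denominator factor vanishes.
#'
#' @param pred,exp Equal-length numeric vectors.
#' @param threshold Class boundary (kcal/mol).
#' @return List with `acc`, `sen`, `spe`, `mcc`.
#' @export
classification_metrics <- function(pred, exp, threshold = 0) {
  if (length(pred) != length(exp) || length(pred) < 1) {
    stop("need two equal-length non-empty vectors")
  }
  pp <- pred < threshold
  ee <- exp < threshold
  tp <- sum(pp & ee); tn <- sum(!pp & !ee)
  fp <- sum(pp & !ee); fn <- sum(!pp & ee)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(acc = (tp + tn) / length(pred),
       sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       mcc = if (den > 0) (tp * tn - fp * fn) / den else 0)
}

#' Anti-symmetry bias metrics
#'
#' `r_di` is the Pearson correlation between paired direct and inverse
#' predictions (-1 means perfect anti-symmetry); `delta_mean` is the mean
#' of the pairwise direct + inverse sums (0 means no systematic bias).
#'
#' @param pred_direct,pred_inverse Paired prediction vectors.
#' @return List with `r_di` and `delta_mean` (kcal/mol).
#' @export
bias_metrics <- function(pred_direct, pred_inverse) {
  if (length(pred_direct) != length(pred_inverse)) stop("pairs must align")
  if (length(pred_direct) < 2) stop("r_di undefined for fewer than 2 pairs")
  list(r_di = stats::cor(pred_direct, pred_inverse),
       delta_mean = mean(pred_direct + pred_inverse))
}

# cache for the SNV reachability table
.gatddg_env <- new.env(parent = emptyenv())

standard_codons <- function() {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required for the genetic-code table")
  }
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

snv_reachability_table <- function() {
  if (!is.null(.gatddg_env$snv_table)) return(.gatddg_env$snv_table)
  codons <- standard_codons()
  aas <- sort(names(AA_THREE))
  tab <- matrix(FALSE, 20, 20, dimnames = list(aas, aas))
  hamming1 <- function(c1, c2) {
    sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]]) == 1
  }
  for (a in aas) {
    for (b in aas) {
      if (a == b) next
      for (ca in codons[[a]]) {
        for (cb in codons[[b]]) {
          if (hamming1(ca, cb)) {
            tab[a, b] <- TRUE
            break
          }
        }
        if (tab[a, b]) break
      }
    }
  }
  .gatddg_env$snv_table <- tab
  tab
}

#' Is an amino-acid substitution reachable by a single nucleotide change?
#'
#' TRUE iff some codon of `wt_aa` differs from some codon of `mut_aa` at
#' exactly one position under the standard genetic code.
#'
#' @param wt_aa,mut_aa One-letter codes (vectorized, equal length).
#' @return Logical vector.
#' @export
is_snv <- function(wt_aa, mut_aa) {
  tab <- snv_reachability_table()
  wt_aa <- toupper(wt_aa)
  mut_aa <- toupper(mut_aa)
  if (any(wt_aa == mut_aa)) stop("wt and mutant residues must differ")
  mapply(function(a, b) tab[a, b], wt_aa, mut_aa, USE.NAMES = FALSE)
}

safe_regression <- function(pred, exp) {
  tryCatch(regression_metrics(pred, exp),
           error = function(e) list(pcc = NA_real_, rmse = NA_real_, mae = NA_real_))
}

stratum_report <- function(pred, exp) {
  c(safe_regression(pred, exp), classification_metrics(pred, exp),
    list(n = length(pred)))
}

#' Full evaluation report
#'
#' Regression and classification metrics overall and per stratum (direct,
#' inverse, and for direct rows SNV vs non-SNV), plus the anti-symmetry
#' bias metrics on direct/inverse pairs.
#'
#' @param predictions data.frame with `pred`, `ddg` (experimental),
#'   `is_inverse`, `pair_id`, and optionally `wt_aa`/`mut_aa` for the SNV
#'   strata.
#' @return An `EvalReport` list.
#' @export
evaluate <- function(predictions) {
  stopifnot(all(c("pred", "ddg", "is_inverse", "pair_id") %in% names(predictions)))
  d <- predictions[!predictions$is_inverse, , drop = FALSE]
  i <- predictions[predictions$is_inverse, , drop = FALSE]
  rep_ <- list(overall = stratum_report(predictions$pred, predictions$ddg),
               direct = stratum_report(d$pred, d$ddg),
               inverse = if (nrow(i)) stratum_report(i$pred, i$ddg) else NULL)
  m <- match(d$pair_id, i$pair_id)
  if (nrow(i) && !anyNA(m) && nrow(d) >= 2) {
    rep_$bias <- bias_metrics(d$pred, i$pred[m])
  } else if (nrow(i)) {
    warning("unpaired direct/inverse rows: bias metrics omitted")
  }
  if (all(c("wt_aa", "mut_aa") %in% names(d)) && nrow(d)) {
    snv <- is_snv(d$wt_aa, d$mut_aa)
    if (sum(snv) >= 2) rep_$snv <- stratum_report(d$pred[snv], d$ddg[snv])
    if (sum(!snv) >= 2) rep_$non_snv <- stratum_report(d$pred[!snv], d$ddg[!snv])
  }
  structure(rep_, class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  fmt <- function(s, nm) {
    if (is.null(s)) return(invisible(NULL))
    cat(sprintf(" %-8s n=%4d  PCC %6.3f  RMSE %5.2f  MAE %5.2f  ACC %5.2f  MCC %6.3f\n",
                nm, s$n, s$pcc, s$rmse, s$mae, s$acc, s$mcc))
  }
  cat("EvalReport\n")
  for (nm in c("overall", "direct", "inverse", "snv", "non_snv")) fmt(x[[nm]], nm)
  if (!is.null(x$bias)) {
    cat(sprintf(" bias     r_di %6.3f  <delta> %6.3f kcal/mol\n",
                x$bias$r_di, x$bias$delta_mean))
  }
  invisible(x)
}
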