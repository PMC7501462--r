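#' Confusion-matrix summary of binary growth predictions
#'
#' "Growth" is the positive class. Any metric with a zero denominator is
#' reported as `NA` (undefined), never silently zero.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return a `confusion_metrics` object (also a one-row tibble) with counts,
#'   `accuracy`, `sensitivity`, `specificity` and `mcc`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  n <- tp + fp + tn + fn
  div <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  out <- tibble(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    accuracy = div(tp + tn, n),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_)
  class(out) <- c("confusion_metrics", class(out))
  out
}

#' @export
tidy.confusion_metrics <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)),
                      dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' Evaluate growth/knockout phenotype tests against a model
#'
#' Each test is simulated by FBA on a copy of the model. For
#' `growth_medium` tests, all exchange uptake bounds are closed and the
#' test's exchanges opened to the stated uptake magnitudes; for `knockout`
#' tests, reactions whose gene rule evaluates false with the deleted genes
#' are blocked. Growth is predicted when the optimum exceeds
#' `growth_cutoff`; infeasible test models count as predicted no-growth.
#'
#' @param model a `metabolic_model`.
#' @param tests tibble with columns `test_id`, `kind` (`"growth_medium"` or
#'   `"knockout"`), `spec` (list column: named numeric of uptake magnitudes
#'   per exchange id, or character vector of deleted genes) and `observed`
#'   (logical, `TRUE` = growth).
#' @param growth_cutoff growth-call threshold, 1/h.
#' @return a [confusion_metrics()] object; the per-test predictions are
#'   attached as attribute `"predictions"`.
#' @export
evaluate_phenotypes <- function(model, tests, growth_cutoff = 1e-6) {
  tests <- as_tibble(tests)
  if (!nrow(tests)) {
    abort("no phenotype tests supplied", class = "switchflux_usage_error")
  }
  exch <- exchange_reactions(model)
  predicted <- vapply(seq_len(nrow(tests)), function(k) {
    spec <- tests$spec[[k]]
    m <- model
    if (tests$kind[k] == "growth_medium") {
      bad <- setdiff(names(spec), exch)
      if (length(bad)) {
        abort(paste0("test '", tests$test_id[k],
                     "' references non-exchange reaction(s): ",
                     paste(bad, collapse = ", ")),
              class = "switchflux_model_error")
      }
      i <- m$reactions$id %in% exch
      m$reactions$lb[i] <- pmax(m$reactions$lb[i], 0)
      m <- set_bounds(m, names(spec), lb = -abs(unlist(spec)))
    } else if (tests$kind[k] == "knockout") {
      bad <- setdiff(spec, model$genes)
      if (length(bad)) {
        abort(paste0("test '", tests$test_id[k], "' deletes unknown gene(s): ",
                     paste(bad, collapse = ", ")),
              class = "switchflux_model_error")
      }
      m <- knockout_genes(m, spec)
    } else {
      abort(paste0("unknown test kind '", tests$kind[k], "'"),
            class = "switchflux_usage_error")
    }
    res <- fba_status(m)
    res$status == "optimal" && res$objective_value > growth_cutoff
  }, logical(1))
  obs <- tests$observed
  cm <- confusion_metrics(tp = sum(predicted & obs),
                          fp = sum(predicted & !obs),
                          tn = sum(!predicted & !obs),
                          fn = sum(!predicted & obs))
  attr(cm, "predictions") <- tibble(test_id = tests$test_id,
                                    observed = obs, predicted = predicted)
  cm
}

#' Recover an integer confusion matrix from rounded summary metrics
#'
#' Exhaustively searches all non-negative integer splits
#' `(tp, fn, tn, fp)` of `n` whose accuracy, sensitivity and specificity
#' round to the given values at `decimals` decimal places (a metric target
#' given as `NA` is not constrained; an undefined metric only matches an
#' `NA` target). This is the brute-force oracle used to recover a printed
#' confusion summary.
#'
#' @param n total number of tests.
#' @param accuracy,sensitivity,specificity rounded target values in `[0,1]`
#'   (or `NA`).
#' @param decimals number of decimals the targets are rounded to.
#' @return tibble of all matching solutions with their exact metrics and
#'   MCC; zero rows when no integer solution exists. Attribute `"unique"`
#'   flags a single match.
#' @export
recover_confusion <- function(n, accuracy = NA, sensitivity = NA,
                              specificity = NA, decimals = 2) {
  stopifnot(n > 0)
  tol <- 0.5 * 10^(-decimals) + 1e-12
  matches_target <- function(value, target) {
    if (is.na(target)) return(rep(TRUE, length(value)))
    !is.na(value) & abs(value - target) <= tol
  }
  out <- vector("list", n + 1)
  for (P in 0:n) {                      # P = observed positives (tp + fn)
    N <- n - P
    tp_all <- 0:P
    sens <- if (P > 0) tp_all / P else rep(NA_real_, length(tp_all))
    tp_ok <- tp_all[matches_target(sens, sensitivity) |
                      (P == 0 & is.na(sensitivity))]
    if (P == 0 && !is.na(sensitivity)) tp_ok <- integer()
    tn_all <- 0:N
    spec <- if (N > 0) tn_all / N else rep(NA_real_, length(tn_all))
    tn_ok <- tn_all[matches_target(spec, specificity)]
    if (N == 0 && !is.na(specificity)) tn_ok <- integer()
    if (!length(tp_ok) || !length(tn_ok)) next
    grid <- expand.grid(tp = tp_ok, tn = tn_ok)
    acc <- (grid$tp + grid$tn) / n
    grid <- grid[matches_target(acc, accuracy), , drop = FALSE]
    if (!nrow(grid)) next
    out[[P + 1]] <- tibble(tp = grid$tp, fn = P - grid$tp,
                           tn = grid$tn, fp = N - grid$tn)
  }
  sol <- bind_rows(out)
  if (nrow(sol)) {
    metrics <- lapply(seq_len(nrow(sol)), function(k) {
      confusion_metrics(sol$tp[k], sol$fp[k], sol$tn[k], sol$fn[k])
    })
    sol <- bind_rows(metrics)
  }
  attr(sol, "unique") <- nrow(sol) == 1
  sol
}
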