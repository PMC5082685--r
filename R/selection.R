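#' Pairwise correlation screening of candidate covariates
#'
#' Pearson correlations on complete cases; any pair at or above the
#' threshold is flagged and resolved by keeping the first-listed covariate
#' (candidate order is the tie-break everywhere in selection). Constant
#' covariates have undefined correlations and are dropped with a warning.
#'
#' @param data segment data.frame.
#' @param covariates character vector of covariate column names, in priority
#'   order.
#' @param threshold absolute-correlation flag level (default 0.35, the level
#'   below which all variables enter the global model).
#' @return list: `correlations` (matrix), `flagged` (data.frame of pairs),
#'   `keep` (surviving covariates), `dropped`.
#' @export
correlation_screen <- function(data, covariates, threshold = 0.35) {
  covariates <- covariates[covariates %in% names(data)]
  X <- data[, covariates, drop = FALSE]
  cc <- stats::complete.cases(X)
  if (sum(cc) < 3) stop("need at least 3 complete segments for screening")
  X <- X[cc, , drop = FALSE]
  const <- vapply(X, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)), TRUE)
  if (any(const)) {
    warning("constant covariate(s) dropped: ",
            paste(names(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  R <- stats::cor(X)
  flagged <- NULL
  keep <- colnames(R)
  dropped <- character(0)
  if (ncol(R) >= 2) {
    for (i in seq_len(ncol(R) - 1)) for (j in (i + 1):ncol(R)) {
      if (abs(R[i, j]) >= threshold) {
        flagged <- rbind(flagged,
                         data.frame(var1 = colnames(R)[i], var2 = colnames(R)[j],
                                    r = R[i, j], stringsAsFactors = FALSE))
        if (colnames(R)[j] %in% keep) {
          keep <- setdiff(keep, colnames(R)[j])
          dropped <- union(dropped, colnames(R)[j])
          message("screening: dropped ", colnames(R)[j], " (|r| = ",
                  sprintf("%.2f", abs(R[i, j])), " with ", colnames(R)[i], ")")
        }
      }
    }
  }
  list(correlations = R, flagged = flagged, keep = keep, dropped = dropped)
}

# build one term's formula fragment
.term_text <- function(cand) {
  if (!is.null(cand$soap)) {
    sprintf("s(%s, %s, bs = \"so\", k = %d, xt = .soap$xt)",
            cand$vars[1], cand$vars[2], cand$k)
  } else if (length(cand$vars) == 2) {
    sprintf("s(%s, %s, bs = \"tp\", k = %d)", cand$vars[1], cand$vars[2], cand$k)
  } else {
    sprintf("s(%s, bs = \"cr\", k = %d)", cand$vars, cand$k)
  }
}

#' Describe a candidate smooth term
#'
#' @param vars one covariate name, or two for a bivariate spatial term.
#' @param k basis dimension (default 10 univariate, 20 bivariate).
#' @param soap optional `"soap_spec"`: the spatial term then uses the
#'   boundary-respecting soap-film basis instead of a thin-plate spline.
#' @param label display label; defaults to the variable names.
#' @return candidate list for [stepwise_select()].
#' @export
candidate_term <- function(vars, k = if (length(vars) == 2) 20 else 10,
                           soap = NULL, label = paste(vars, collapse = ",")) {
  stopifnot(length(vars) %in% 1:2)
  list(vars = vars, k = k, soap = soap, label = label)
}

#' Forward/backward smooth-term selection
#'
#' Starting from the intercept-only model, each step adds the single
#' candidate whose addition gives the lowest REML score, then removes any
#' retained term whose approximate p-value exceeds `alpha`. Selection stops
#' when no addition improves REML and every retained term is significant.
#' The trace records every model tried. Deterministic given data and
#' candidate order.
#'
#' @param data annotated segment data.frame with a `count` column.
#' @param candidates list of [candidate_term()]s, in priority order.
#' @param family a [dsm_family()].
#' @param alpha significance level for the backward step (default 0.05).
#' @param offset_var effort-area column name.
#' @return list: `fit` (final `"dsm_fit"`), `terms` (retained labels),
#'   `trace` (data.frame: step, action, term, reml, edf, p_value).
#' @export
stepwise_select <- function(data, candidates, family = dsm_family("nb"),
                            alpha = 0.05, offset_var = "area") {
  labels <- vapply(candidates, function(cn) cn$label, "")
  if (anyDuplicated(labels)) stop("candidate labels must be unique")
  names(candidates) <- labels
  env <- new.env(parent = parent.frame())
  soaps <- Filter(function(cn) !is.null(cn$soap), candidates)
  if (length(soaps) > 1) stop("at most one soap-film candidate is supported")
  knots <- NULL
  if (length(soaps)) {
    assign(".soap", soaps[[1]]$soap, envir = env)
    knots <- soaps[[1]]$soap$knots
  }
  fit_model <- function(in_labels) {
    rhs <- if (length(in_labels)) {
      paste(vapply(candidates[in_labels], .term_text, ""), collapse = " + ")
    } else "1"
    f <- stats::as.formula(paste("count ~", rhs), env = env)
    fit_gam(f, data, family = family, offset_var = offset_var, knots = knots)
  }
  current <- character(0)
  fit <- fit_model(current)
  trace <- data.frame(step = 0L, action = "start", term = "(intercept)",
                      reml = fit$reml, edf = fit$total_edf, p_value = NA,
                      stringsAsFactors = FALSE)
  step <- 0L
  dropped_ever <- character(0)
  repeat {
    step <- step + 1L
    before <- current
    # forward: try each remaining candidate (never re-offer a term the
    # backward step has discarded -- prevents add/remove cycling)
    remaining <- setdiff(labels, c(current, dropped_ever))
    if (!length(remaining)) break
    trials <- lapply(remaining, function(lb) {
      tryCatch(fit_model(c(current, lb)), error = function(e) NULL)
    })
    names(trials) <- remaining
    trials <- Filter(Negate(is.null), trials)
    if (!length(trials)) break
    remls <- vapply(trials, function(f) f$reml, 0)
    for (lb in names(trials))
      trace <- rbind(trace, data.frame(step = step, action = "try", term = lb,
                                       reml = trials[[lb]]$reml,
                                       edf = trials[[lb]]$total_edf,
                                       p_value = NA))
    best <- names(trials)[which.min(remls)]
    if (min(remls) >= fit$reml) break          # no addition improves REML
    current <- c(current, best)
    fit <- trials[[best]]
    trace <- rbind(trace, data.frame(step = step, action = "add", term = best,
                                     reml = fit$reml, edf = fit$total_edf,
                                     p_value = NA))
    # backward: drop non-significant terms (worst first)
    repeat {
      pv <- approx_pvalue(fit)
      ord <- match(vapply(candidates[current], .smooth_label, "",
                          data = data), pv$term)
      pvals <- pv$p_value[ord]
      if (all(pvals <= alpha, na.rm = TRUE)) break
      worst <- current[which.max(pvals)]
      current <- setdiff(current, worst)
      dropped_ever <- union(dropped_ever, worst)
      fit <- fit_model(current)
      trace <- rbind(trace, data.frame(step = step, action = "remove",
                                       term = worst, reml = fit$reml,
                                       edf = fit$total_edf,
                                       p_value = max(pvals, na.rm = TRUE)))
      if (!length(current)) break
    }
    if (setequal(current, before)) break
  }
  if (!length(current))
    warning("no candidate was significant; returning the intercept-only model")
  list(fit = fit, terms = current, trace = trace)
}

# mgcv smooth label for a candidate ("s(depth)" / "s(cx,cy)")
.smooth_label <- function(cand, data) {
  paste0("s(", paste(cand$vars, collapse = ","), ")")
}

#' Write a selection trace CSV
#'
#' @param selection result of [stepwise_select()].
#' @param path CSV path.
#' @export
write_selection_trace <- function(selection, path) {
  utils::write.csv(selection$trace, path, row.names = FALSE)
  invisible(path)
}
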