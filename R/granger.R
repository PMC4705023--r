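# Granger causality: per-model Wald tests on the cause variable's lag
# coefficients in the effect equation, per-model sign classification, and
# aggregation across all valid models into weighted, signed directed edges.

granger_terms <- function(fit, cause, effect) {
  terms <- paste0(cause, ".l", seq_len(fit$spec$lag))
  con <- fit$constraints$term[fit$constraints$equation == effect]
  setdiff(terms, con)
}

#' Granger-causality Wald test within one fitted model
#'
#' Tests the joint null that every unconstrained coefficient of the cause
#' variable's lags in the effect variable's equation is zero, using the
#' equation's classical OLS coefficient covariance; the statistic is referred
#' to a chi-square with df equal to the number of such coefficients. When
#' pruning has already constrained all of them, the null holds by
#' construction and `W = 0, df = 0, p = 1` is returned with
#' `all_constrained = TRUE`.
#'
#' @param fit A `var_fit` estimated with inference.
#' @param cause,effect Endogenous variable labels (distinct).
#' @return List with `statistic`, `df`, `p_value`, `terms`,
#'   `all_constrained`.
#' @export
granger_wald <- function(fit, cause, effect) {
  stopifnot(cause %in% fit$variables, effect %in% fit$variables)
  if (cause == effect) abort("cause and effect must differ")
  free <- granger_terms(fit, cause, effect)
  if (length(free) == 0) {
    return(list(statistic = 0, df = 0L, p_value = 1, terms = character(0),
                all_constrained = TRUE))
  }
  b <- fit$coefficients[free, effect]
  vb <- fit$cov[[effect]][free, free, drop = FALSE]
  w <- as.numeric(t(b) %*% solve(vb, b))
  list(statistic = w, df = length(free),
       p_value = stats::pchisq(w, df = length(free), lower.tail = FALSE),
       terms = free, all_constrained = FALSE)
}

#' Sign of a Granger association within one model
#'
#' Classifies the signs of the unconstrained cause-lag coefficients in the
#' effect equation: all positive, all negative, or mixed within the model
#' (positive and negative estimates at different lags).
#'
#' @inheritParams granger_wald
#' @return `"positive"`, `"negative"` or `"mixed_within"`.
#' @export
sign_classify <- function(fit, cause, effect) {
  free <- granger_terms(fit, cause, effect)
  if (length(free) == 0) {
    abort("all cause-lag coefficients are constrained; no sign defined")
  }
  b <- fit$coefficients[free, effect]
  if (all(b > 0)) "positive" else if (all(b < 0)) "negative" else "mixed_within"
}

#' Aggregate Granger tests across all valid models
#'
#' For every ordered pair of endogenous variables, the edge weight is the
#' proportion of valid models in which the Wald test is significant at
#' `alpha` (denominator: all valid models; a model whose cause-lags are fully
#' constrained contributes a non-significant verdict). Edges with zero
#' proportion are not emitted. The sign class is the common per-model class
#' of the contributing (significant) models, or `"mixed_across"` when they
#' disagree; `best_model_p` is the Wald p-value in the highest-ranked
#' contributing model.
#'
#' Per-model tests run on the *unpruned* fit of each valid specification:
#' pruning is a data-driven selection step, and a Wald test restricted to the
#' coefficients that survived selection roughly doubles its false-positive
#' rate (the surviving coefficient is the most significant of its block), so
#' the full cause-lag block as originally estimated is tested instead. The
#' pruned model remains the model that is reported and gated.
#'
#' @param search A `var_search` from [run_search()].
#' @param alpha Significance level for edge inclusion; defaults to the
#'   search's alpha.
#' @return A `granger_summary` with `edges` (cause, effect, proportion,
#'   sign_class, best_model_p), the per-model `detail` table, and `none`
#'   (`TRUE` when no significant association exists in any valid model).
#' @export
summarize_granger <- function(search, alpha = NULL) {
  alpha <- alpha %||% search$alpha
  vm <- valid_models(search)
  vars <- search$variables
  pairs <- expand.grid(cause = vars, effect = vars,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$cause != pairs$effect, , drop = FALSE]
  pairs <- pairs[order(match(pairs$cause, vars), match(pairs$effect, vars)), ]

  use_unpruned <- "fit_unpruned" %in% names(vm)
  detail <- purrr::map_dfr(seq_len(nrow(vm)), function(i) {
    fit <- if (use_unpruned && !is.null(vm$fit_unpruned[[i]])) {
      vm$fit_unpruned[[i]]
    } else {
      vm$fit[[i]]
    }
    purrr::map_dfr(seq_len(nrow(pairs)), function(j) {
      gw <- granger_wald(fit, pairs$cause[j], pairs$effect[j])
      tibble::tibble(
        rank = vm$rank[i], model_id = vm$id[i],
        cause = pairs$cause[j], effect = pairs$effect[j],
        statistic = gw$statistic, df = gw$df, p_value = gw$p_value,
        significant = gw$p_value < alpha,
        sign = if (gw$all_constrained) NA_character_ else
          sign_classify(fit, pairs$cause[j], pairs$effect[j]))
    })
  })

  edges <- if (nrow(detail) == 0) {
    tibble::tibble(cause = character(), effect = character(),
                   proportion = numeric(), sign_class = character(),
                   best_model_p = numeric())
  } else {
    detail |>
      dplyr::group_by(.data$cause, .data$effect) |>
      dplyr::summarise(
        proportion = mean(.data$significant),
        sign_class = {
          s <- unique(.data$sign[.data$significant])
          if (length(s) == 0) NA_character_
          else if (length(s) == 1) s
          else "mixed_across"
        },
        best_model_p = if (any(.data$significant)) {
          .data$p_value[.data$significant][
            which.min(.data$rank[.data$significant])]
        } else NA_real_,
        .groups = "drop") |>
      dplyr::filter(.data$proportion > 0) |>
      dplyr::arrange(match(.data$cause, vars), match(.data$effect, vars))
  }

  structure(list(edges = edges, detail = detail, n_valid = nrow(vm),
                 alpha = alpha, variables = vars,
                 none = nrow(edges) == 0),
            class = "granger_summary")
}

#' @export
print.granger_summary <- function(x, ...) {
  if (x$none) {
    cat("Granger causality summary: none.\n")
    return(invisible(x))
  }
  cat("Granger causality summary (", x$n_valid, " valid models):\n", sep = "")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s -> %s: %s, in %.0f%% of valid models (best-model p = %.3g)\n",
                e$cause, e$effect, e$sign_class, 100 * e$proportion,
                e$best_model_p))
  }
  invisible(x)
}

#' Tidy the edges of a Granger summary
#'
#' @param x A `granger_summary`.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.granger_summary <- function(x, ...) x$edges
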