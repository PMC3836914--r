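# Ranking and rejection of candidates. Two mechanisms, usable alone or
# combined: (1) a stable iterative prioritised sort with per-characteristic
# rejection thresholds and a sub-optimal fallback, and (2) a weighted
# multi-objective score F = sum_i w_i * g(x_i) with the sigmoid
# g(x) = 1 / (1 + exp(-k (x - o))) as the non-linear component. All raw
# characteristics are normalised to penalties where 0 is ideal and larger is
# worse, so F is minimised.

#' Sigmoid non-linearity
#'
#' \code{1 / (1 + exp(-gain * (x - offset)))}; strictly increasing in x,
#' equal to 0.5 at \code{x = offset}, saturating at 0 and 1. The gain
#' adjusts how sharply the sigmoid discriminates around the offset
#' (default 1.0); the offset shifts penalties into the steep region.
#'
#' @param x penalty value(s).
#' @param gain gain term k > 0 (default 1.0).
#' @param offset offset o (default 0).
#' @return value(s) in (0, 1).
#' @export
sigmoid <- function(x, gain = 1.0, offset = 0) {
  stopifnot(gain > 0)
  1 / (1 + exp(-gain * (x - offset)))
}

#' Define a selection characteristic
#'
#' Names a candidate/pair quality dimension with its rejection threshold,
#' sort priority and multi-objective parameters. Built-in names and their
#' penalty normalisations (0 = ideal):
#' \describe{
#'   \item{tm_deviation}{|tm - preferred_tm| (mean of forward/reverse for
#'     pairs)}
#'   \item{gc_deviation}{|gc - preferred_gc| (mean for pairs)}
#'   \item{hairpin, self_dimer, pair_dimer}{raw rule-based scores (max of
#'     forward/reverse for pairs where per-primer)}
#'   \item{binding_excess}{max(0, binding_count - 1): sites beyond the
#'     intended locus}
#'   \item{products_excess}{max(0, products_count - 1): products beyond the
#'     target amplicon}
#'   \item{length_deviation}{|length - length_optimum|}
#'   \item{tm_difference, gc_difference, length_difference}{pair-level
#'     similarity penalties, used raw}
#' }
#'
#' @param name built-in name above, or any column of the candidate frame
#'   (used raw), or supply \code{penalty_fun}.
#' @param priority sort rank; priority 1 is the most important
#'   characteristic (sorted last, so it dominates).
#' @param threshold candidates with penalty strictly above this are rejected
#'   in prioritised mode (default Inf: no rejection).
#' @param weight multi-objective weight w >= 0 (default 1).
#' @param gain sigmoid gain k > 0 (default 1.0).
#' @param offset sigmoid offset o (default 0; set near the midpoint of the
#'   penalty distribution for best discrimination).
#' @param penalty_fun optional function(data.frame) -> numeric penalties,
#'   overriding the built-in normalisation.
#' @return an object of class \code{sel_characteristic}.
#' @export
characteristic <- function(name, priority, threshold = Inf, weight = 1,
                           gain = 1.0, offset = 0, penalty_fun = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            weight >= 0, gain > 0)
  structure(list(name = name, priority = as.integer(priority),
                 threshold = threshold, weight = weight, gain = gain,
                 offset = offset, penalty_fun = penalty_fun),
            class = "sel_characteristic")
}

#' Selection specification
#'
#' @param characteristics list of \code{\link{characteristic}} objects with
#'   unique priorities; at least one.
#' @param method \code{"prioritised"}, \code{"multi_objective"}, or
#'   \code{"prioritised_then_multi_objective"} (thresholded prioritised
#'   sorting first, multi-objective refinement of the survivors as the last
#'   step).
#' @param keep_suboptimal if thresholding would reject every candidate,
#'   retain them all, flagged sub-optimal, instead of returning none
#'   (default TRUE).
#' @param preferred_tm,preferred_gc,length_optimum reference values used by
#'   the built-in penalty normalisations.
#' @return an object of class \code{selection_spec}.
#' @export
selection_spec <- function(characteristics,
                           method = c("prioritised", "multi_objective",
                                      "prioritised_then_multi_objective"),
                           keep_suboptimal = TRUE,
                           preferred_tm = 60, preferred_gc = 0.5,
                           length_optimum = NULL) {
  method <- match.arg(method)
  if (inherits(characteristics, "sel_characteristic")) {
    characteristics <- list(characteristics)
  }
  stopifnot(length(characteristics) >= 1L,
            all(vapply(characteristics, inherits, logical(1),
                       "sel_characteristic")))
  prio <- vapply(characteristics, function(ch) ch$priority, integer(1))
  if (anyDuplicated(prio)) stop("characteristic priorities must be unique",
                                call. = FALSE)
  structure(list(characteristics = characteristics, method = method,
                 keep_suboptimal = isTRUE(keep_suboptimal),
                 preferred_tm = preferred_tm, preferred_gc = preferred_gc,
                 length_optimum = length_optimum),
            class = "selection_spec")
}

.col_or_pair <- function(df, col) {
  if (col %in% names(df)) return(df[[col]])
  f <- paste0("forward_", col); r <- paste0("reverse_", col)
  if (f %in% names(df) && r %in% names(df)) {
    return(list(forward = df[[f]], reverse = df[[r]]))
  }
  NULL
}

.penalty_for <- function(df, ch, spec) {
  if (!is.null(ch$penalty_fun)) return(ch$penalty_fun(df))
  nm <- ch$name
  mean2 <- function(v) if (is.list(v)) (v$forward + v$reverse) / 2 else v
  max2 <- function(v) if (is.list(v)) pmax(v$forward, v$reverse) else v
  val <- switch(nm,
    tm_deviation = {
      v <- .col_or_pair(df, "tm")
      if (is.null(v)) NULL else mean2(if (is.list(v)) {
        list(forward = abs(v$forward - spec$preferred_tm),
             reverse = abs(v$reverse - spec$preferred_tm))
      } else abs(v - spec$preferred_tm))
    },
    gc_deviation = {
      v <- .col_or_pair(df, "gc")
      if (is.null(v)) NULL else mean2(if (is.list(v)) {
        list(forward = abs(v$forward - spec$preferred_gc),
             reverse = abs(v$reverse - spec$preferred_gc))
      } else abs(v - spec$preferred_gc))
    },
    hairpin = { v <- .col_or_pair(df, "hairpin"); if (is.null(v)) NULL else max2(v) },
    self_dimer = { v <- .col_or_pair(df, "self_dimer"); if (is.null(v)) NULL else max2(v) },
    pair_dimer = if ("pair_dimer" %in% names(df)) df$pair_dimer else NULL,
    binding_excess = {
      v <- .col_or_pair(df, "binding_count")
      if (is.null(v)) NULL else {
        if (is.list(v)) pmax(pmax(0, v$forward - 1), pmax(0, v$reverse - 1))
        else pmax(0, v - 1)
      }
    },
    products_excess = if ("products_count" %in% names(df))
      pmax(0, df$products_count - 1) else NULL,
    length_deviation = {
      v <- .col_or_pair(df, "length")
      opt <- spec$length_optimum
      if (is.null(v) || is.null(opt)) NULL else
        mean2(if (is.list(v)) list(forward = abs(v$forward - opt),
                                   reverse = abs(v$reverse - opt))
              else abs(v - opt))
    },
    if (nm %in% names(df)) df[[nm]] else NULL)
  if (is.null(val)) {
    stop(sprintf("characteristic '%s' cannot be computed: missing from the candidate data",
                 nm), call. = FALSE)
  }
  as.numeric(val)
}

# penalty matrix: one column per characteristic, 0 = ideal
penalty_matrix <- function(df, spec) {
  cols <- lapply(spec$characteristics, .penalty_for, df = df, spec = spec)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(spec$characteristics, function(ch) ch$name, character(1))
  m
}

#' Multi-objective score
#'
#' \code{F = sum_i w_i * sigmoid(x_i, k_i, o_i)} over the spec's
#' characteristics, where x_i are penalties (0 = ideal). Lower F is better.
#' F is invariant under permutation of the characteristics list.
#'
#' @param df evaluated candidate or pair data.frame.
#' @param spec a \code{selection_spec}.
#' @return numeric vector of scores, one per row of \code{df}.
#' @export
multi_objective_score <- function(df, spec) {
  stopifnot(inherits(spec, "selection_spec"))
  if (nrow(df) == 0L) return(numeric())
  pen <- penalty_matrix(df, spec)
  f <- numeric(nrow(df))
  for (i in seq_along(spec$characteristics)) {
    ch <- spec$characteristics[[i]]
    f <- f + ch$weight * sigmoid(pen[, i], ch$gain, ch$offset)
  }
  f
}

# explicit stable order: ties broken by current position
.stable_order <- function(key) order(key, seq_along(key))

#' Sort, threshold and rank candidates
#'
#' Prioritised mode iterates the characteristics from lowest to highest
#' priority (i.e. least important first); each pass first moves candidates
#' whose penalty exceeds that characteristic's threshold to the bottom and
#' marks them rejected, then stable-sorts the survivors by penalty, so the
#' priority-1 characteristic dominates the final order. If a threshold would
#' reject every remaining candidate and \code{keep_suboptimal} is set, the
#' violators are retained, flagged sub-optimal, and still ordered -- the
#' best available sub-optimal candidates rather than none at all.
#' Multi-objective mode (alone, or as the final refinement step in the
#' combined mode) orders surviving candidates by ascending F.
#'
#' @param cands evaluated candidate or pair data.frame.
#' @param spec a \code{selection_spec}.
#' @return \code{cands} reordered, with logical columns \code{rejected} and
#'   \code{suboptimal}, integer \code{rank} (NA for rejected rows) and, when
#'   multi-objective scoring ran, \code{score_f}.
#' @export
sort_candidates <- function(cands, spec) {
  stopifnot(is.data.frame(cands), inherits(spec, "selection_spec"))
  n <- nrow(cands)
  if (n == 0L) {
    cands$rejected <- logical(); cands$suboptimal <- logical()
    cands$rank <- integer()
    return(cands)
  }
  pen <- penalty_matrix(cands, spec)
  idx <- seq_len(n)               # current order (row indices of cands)
  rejected <- rep(FALSE, n)
  suboptimal <- rep(FALSE, n)

  if (spec$method %in% c("prioritised", "prioritised_then_multi_objective")) {
    prio <- vapply(spec$characteristics, function(ch) ch$priority, integer(1))
    for (ci in order(prio, decreasing = TRUE)) {   # least important first
      ch <- spec$characteristics[[ci]]
      alive <- idx[!rejected[idx]]
      if (length(alive) == 0L) break
      p_alive <- pen[alive, ci]
      viol <- p_alive > ch$threshold
      if (all(viol) && spec$keep_suboptimal) {
        suboptimal[alive] <- TRUE            # retain rather than empty the list
      } else {
        rejected[alive[viol]] <- TRUE
        alive <- alive[!viol]
        p_alive <- p_alive[!viol]
      }
      alive <- alive[.stable_order(pen[alive, ci])]
      idx <- c(alive, idx[rejected[idx]])
    }
  }

  score_f <- NULL
  if (spec$method %in% c("multi_objective", "prioritised_then_multi_objective")) {
    score_f <- multi_objective_score(cands, spec)
    alive <- idx[!rejected[idx]]
    alive <- alive[.stable_order(score_f[alive])]
    idx <- c(alive, idx[rejected[idx]])
  }

  out <- cands[idx, , drop = FALSE]
  out$rejected <- rejected[idx]
  out$suboptimal <- suboptimal[idx]
  out$rank <- ifelse(out$rejected, NA_integer_, cumsum(!out$rejected))
  if (!is.null(score_f)) out$score_f <- score_f[idx]
  rownames(out) <- NULL
  attr(out, "suboptimal_fallback") <- any(suboptimal)
  out
}
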