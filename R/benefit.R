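#' Survival benefit parameters of somatic investment
#'
#' Somatic cells are assumed to raise group survival through recurrent
#' stress events occurring every \code{ts} time units (same units as the
#' development time, one cellular generation = 1). Survival is linear in
#' germ investment: an all-germ group survives a stress event with
#' probability \code{sg}, an all-soma group with probability \code{ss};
#' a benefit to soma exists when \code{sg < ss}. \code{sg = ss} is the
#' degenerate no-benefit case.
#'
#' @param sg survival fraction of an all-germ group per event, in (0, 1].
#' @param ss survival fraction of an all-soma group per event, in (0, 1].
#' @param ts time between stress events (> 0), in cellular-generation units.
#' @return Object of class \code{"survival_params"}.
#' @examples
#' survival_params(sg = 0.5, ss = 1, ts = 5)
#' @export
survival_params <- function(sg, ss, ts) {
  stopifnot(is.numeric(sg), is.numeric(ss), is.numeric(ts),
            length(sg) == 1L, length(ss) == 1L, length(ts) == 1L)
  if (is.na(sg) || sg <= 0 || sg > 1) stop("sg must lie in (0, 1]", call. = FALSE)
  if (is.na(ss) || ss <= 0 || ss > 1) stop("ss must lie in (0, 1]", call. = FALSE)
  if (is.na(ts) || ts <= 0) stop("ts must be > 0", call. = FALSE)
  if (sg > ss)
    stop("sg must not exceed ss (soma cannot reduce survival in this model)",
         call. = FALSE)
  structure(list(sg = sg, ss = ss, ts = ts), class = "survival_params")
}

#' @export
print.survival_params <- function(x, ...) {
  cat(sprintf("Stress survival: sg = %g (all germ), ss = %g (all soma), every ts = %g time units\n",
              x$sg, x$ss, x$ts))
  invisible(x)
}

#' Group survival of a stress event
#'
#' Linear survival function s(pg) = ss + (sg - ss) * pg: survival
#' interpolates between the all-soma value at pg = 0 and the all-germ
#' value at pg = 1.
#'
#' @param pg germ fraction(s) in [0, 1] (0 allowed: a sterile all-soma
#'   group still has a survival probability).
#' @param params a [survival_params] object.
#' @return Survival fraction(s) in (0, 1].
#' @examples
#' group_survival(0.5, survival_params(0.5, 1, 5))  # 0.75
#' @export
group_survival <- function(pg, params) {
  stopifnot(inherits(params, "survival_params"))
  if (!is.numeric(pg) || anyNA(pg) || any(pg < 0) || any(pg > 1))
    stop("pg must lie in [0, 1]", call. = FALSE)
  params$ss + (params$sg - params$ss) * pg
}

#' Net population growth rate under recurring stress
#'
#' The exponential rate implied by the population equation
#' P(t) = P(0) (N pg)^(t/tau) s(pg)^(t/ts):
#' \deqn{r_{net} = \ln(N p_g)/\log_2 N + \ln s(p_g)/t_s.}
#' Reduces to [growth_rate] when survival is certain (sg = ss = 1).
#'
#' @inheritParams life_cycle
#' @param params a [survival_params] object.
#' @return Net growth rate per unit time (may be negative).
#' @examples
#' net_growth_rate(1024, 2/3, survival_params(0.5, 1, 5))
#' @export
net_growth_rate <- function(N, pg = NULL, params) {
  v <- as_np(N, pg)
  s <- group_survival(v$pg, params)
  if (any(s <= 0)) stop("survival must be positive", call. = FALSE)
  log(v$N * v$pg) / log2(v$N) + log(s) / params$ts
}

#' Critical stress interval for somatic specialization
#'
#' The threshold ts* = (ss/sg - 1) * log2(N): when stress recurs more often
#' than this (ts < ts*), groups investing in soma outgrow all-germ groups.
#' The threshold grows with organism size, so larger groups need less
#' frequent stress to favor specialization.
#'
#' @param N adult cell number(s), >= 2.
#' @param params a [survival_params] object with \code{sg < ss}.
#' @return Critical interval(s) ts*, cellular-generation units.
#' @examples
#' critical_ts(1024, survival_params(0.5, 1, 5))  # 10
#' @export
critical_ts <- function(N, params) {
  stopifnot(inherits(params, "survival_params"))
  if (params$sg >= params$ss)
    stop("ts* undefined when sg >= ss: soma is never favored", call. = FALSE)
  if (any(N < 2)) stop("N must be >= 2", call. = FALSE)
  (params$ss / params$sg - 1) * log2(N)
}

#' Optimal germ allocation under stress
#'
#' Maximizes [net_growth_rate] over the germ fraction. The interior
#' optimum has the closed form
#' \deqn{p_g^* = \frac{s_s/(s_s - s_g)}{1 + \log_2(N)/t_s},}
#' clamped to the feasible interval [1/N, 1]; the unclamped value is also
#' returned because the critical interval ts* is defined by where it
#' crosses 1. When sg = ss soma carries cost but no benefit and the
#' optimum is pg = 1. Soma is favored (pg* < 1) exactly when ts < ts*,
#' with the tie ts = ts* counted as not favored.
#'
#' @param N adult cell number(s), >= 2 (vectorized).
#' @param params a [survival_params] object.
#' @return Object of class \code{"germ_optimum"}: a data frame with
#'   columns \code{N}, \code{pg_star}, \code{pg_star_unclamped},
#'   \code{ts_star}, \code{soma_favored}, \code{net_rate}.
#' @examples
#' optimal_allocation(1024, survival_params(0.5, 1, 5))   # pg* = 2/3
#' optimal_allocation(1024, survival_params(0.5, 1, 10))  # boundary: pg* = 1
#' @export
optimal_allocation <- function(N, params) {
  stopifnot(inherits(params, "survival_params"))
  if (!is.numeric(N) || anyNA(N) || any(N < 2))
    stop("N must be numeric and >= 2", call. = FALSE)
  N <- as.numeric(N)
  if (params$sg == params$ss) {
    # degenerate branch: no survival benefit, cost only
    raw <- rep(Inf, length(N))
    star <- rep(1, length(N))
    tss <- rep(NA_real_, length(N))
    fav <- rep(FALSE, length(N))
  } else {
    raw <- (params$ss / (params$ss - params$sg)) /
      (1 + log2(N) / params$ts)
    star <- pmin(1, pmax(1 / N, raw))
    tss <- critical_ts(N, params)
    fav <- params$ts < tss
  }
  rate <- net_growth_rate(N, star, params)
  structure(data.frame(N = N, pg_star = star, pg_star_unclamped = raw,
                       ts_star = tss, soma_favored = fav, net_rate = rate),
            class = c("germ_optimum", "data.frame"))
}

#' @export
print.germ_optimum <- function(x, digits = 4, ...) {
  cat("Optimal germ allocation under recurring stress\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Does larger size raise fitness at fixed specialization?
#'
#' Checks the positive-feedback property: at a fixed germ fraction
#' pg < 1, the intrinsic growth rate increases with organism size, so a
#' lineage already investing in soma gains by growing larger. At pg = 1
#' the rate is ln 2 at every size and the check returns FALSE.
#'
#' @param pg shared germ fraction, with \code{1/N1 <= pg <= 1}.
#' @param N1,N2 two sizes with \code{N1 < N2}.
#' @return TRUE iff growth_rate(N2, pg) > growth_rate(N1, pg).
#' @examples
#' size_feedback_check(0.1, 100, 1e4)  # TRUE
#' size_feedback_check(1, 100, 1e4)    # FALSE: equal at ln 2
#' @export
size_feedback_check <- function(pg, N1, N2) {
  if (N1 >= N2) stop("require N1 < N2", call. = FALSE)
  growth_rate(N2, pg) > growth_rate(N1, pg)
}
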