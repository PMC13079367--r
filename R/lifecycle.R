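#' Life cycle of a clonally developing organism
#'
#' Constructs a validated description of a multicellular life cycle: an
#' organism develops from a unicellular propagule by synchronized cell
#' divisions to adult size \code{N}, of which a proportion \code{pg} are
#' germ cells (propagules for the next generation) and the remainder are
#' somatic cells discarded at reproduction.
#'
#' \code{N} is treated as real-valued so that cost surfaces can be
#' evaluated on a continuum; integer species counts are promoted. The germ
#' fraction must respect the theoretical minimum of one germ cell,
#' \code{pg >= 1/N}.
#'
#' @param N adult cell number; real, \code{N >= 2}.
#' @param pg germ fraction at maturity; \code{1/N <= pg <= 1}.
#' @return An object of class \code{"life_cycle"}: a list with elements
#'   \code{N} and \code{pg} (recycled to common length).
#' @examples
#' lc <- life_cycle(N = 2048, pg = 8 / 2048)  # Volvox aureus
#' lc
#' @export
life_cycle <- function(N, pg) {
  check_lifecycle(N, pg)
  n <- max(length(N), length(pg))
  out <- list(N = rep_len(as.numeric(N), n), pg = rep_len(as.numeric(pg), n))
  class(out) <- "life_cycle"
  out
}

check_lifecycle <- function(N, pg) {
  if (!is.numeric(N) || !is.numeric(pg) || length(N) == 0L || length(pg) == 0L)
    stop("N and pg must be non-empty numeric", call. = FALSE)
  if (anyNA(N) || anyNA(pg))
    stop("N and pg must not contain NA", call. = FALSE)
  if (any(N < 2))
    stop("N must be >= 2 (at least one cell division)", call. = FALSE)
  if (any(pg <= 0) || any(pg > 1))
    stop("pg must lie in (0, 1]", call. = FALSE)
  if (any(pg * N < 1 - 1e-12))
    stop("pg below the one-germ-cell minimum 1/N", call. = FALSE)
  invisible(TRUE)
}

# accept either a life_cycle object or raw (N, pg); returns list(N, pg)
as_np <- function(N, pg = NULL) {
  if (inherits(N, "life_cycle")) return(N[c("N", "pg")])
  check_lifecycle(N, pg)
  list(N = as.numeric(N), pg = as.numeric(pg))
}

#' Development time in cellular generations
#'
#' Clonal development from one cell to size \code{N} by synchronized
#' divisions takes \code{log2(N)} rounds of division. Fractional values are
#' meaningful for non-power-of-two sizes.
#'
#' @param N adult cell number (\code{N >= 2}), or a [life_cycle] object.
#' @return Development time tau in cellular generations (>= 1 for N >= 2).
#' @examples
#' development_time(2048)  # 11 generations
#' @export
development_time <- function(N) {
  if (inherits(N, "life_cycle")) N <- N$N
  if (!is.numeric(N) || anyNA(N) || any(N < 2))
    stop("N must be numeric and >= 2", call. = FALSE)
  log2(N)
}

#' Intrinsic population growth rate
#'
#' The per-unit-time exponential growth rate of a population of organisms
#' with life cycle (N, pg): each life cycle lasts tau = log2(N) time units
#' and multiplies the population by N*pg, giving r = ln(N*pg)/log2(N).
#' When pg = 1 this is ln 2 regardless of N; it is zero when N*pg = 1
#' (one propagule per generation).
#'
#' @inheritParams life_cycle
#' @return Growth rate per unit time (one cellular generation = 1 unit).
#' @examples
#' growth_rate(2048, 8 / 2048)
#' growth_rate(1e6, 1)  # ln 2, independent of size
#' @export
growth_rate <- function(N, pg = NULL) {
  v <- as_np(N, pg)
  log(v$N * v$pg) / log2(v$N)
}

#' Proportional growth-rate cost of somatic specialization
#'
#' The fractional reduction in growth rate relative to an undifferentiated
#' organism of the same size: 1 - r/rmax = -ln(pg)/ln(N). The cost of a
#' fixed somatic allocation shrinks as organisms get larger, because the
#' same proportional reproductive loss is diluted over more doublings of
#' development.
#'
#' @inheritParams life_cycle
#' @return Dimensionless cost in [0, 1); 0 iff pg = 1.
#' @examples
#' specialization_cost(100, 0.1)   # 0.50
#' specialization_cost(1e4, 0.1)   # 0.25
#' specialization_cost(1e6, 0.1)   # 0.1667
#' @export
specialization_cost <- function(N, pg = NULL) {
  v <- as_np(N, pg)
  -log(v$pg) / log(v$N)
}

#' Fold reduction in growth rate
#'
#' The factor rmax / r = ln(N) / ln(N*pg) by which specialization slows
#' exponential growth relative to an all-germ organism of the same size.
#' Defined only for growing populations (N*pg > 1); equals
#' 1 / (1 - specialization_cost).
#'
#' @inheritParams life_cycle
#' @return Fold reduction (>= 1). Full precision; round for presentation.
#' @examples
#' fold_reduction(2048, 8 / 2048)  # 11/3, i.e. 3.7-fold slower
#' @export
fold_reduction <- function(N, pg = NULL) {
  v <- as_np(N, pg)
  if (any(v$N * v$pg <= 1 + 1e-15))
    stop("fold reduction undefined for non-growing life cycle (N*pg <= 1)",
         call. = FALSE)
  log(v$N) / log(v$N * v$pg)
}

#' Fold-reduction surface over size and germ fraction
#'
#' Evaluates [fold_reduction] on the grid \code{N_grid} x \code{pg_grid}.
#' Grid entries below the one-germ-cell line (pg < 1/N) are masked rather
#' than dropped; entries on the non-growing boundary (N*pg <= 1) come out
#' infinite.
#'
#' @param N_grid sizes (all >= 2).
#' @param pg_grid germ fractions in (0, 1].
#' @return Object of class \code{"cost_surface"}: list with the fold matrix
#'   (rows = N, cols = pg), a logical \code{masked} matrix, and the grids.
#' @examples
#' cs <- cost_surface(c(1e2, 1e4, 1e6), c(0.1, 0.5, 1))
#' cs$fold
#' @export
cost_surface <- function(N_grid, pg_grid) {
  if (length(N_grid) == 0L || length(pg_grid) == 0L)
    stop("empty grid", call. = FALSE)
  if (any(N_grid < 2)) stop("N_grid entries must be >= 2", call. = FALSE)
  if (any(pg_grid <= 0) || any(pg_grid > 1))
    stop("pg_grid entries must lie in (0, 1]", call. = FALSE)
  N <- as.numeric(N_grid); pg <- as.numeric(pg_grid)
  Nm <- matrix(N, length(N), length(pg))
  Pm <- matrix(pg, length(N), length(pg), byrow = TRUE)
  masked <- Pm < 1 / Nm
  fold <- log(Nm) / log(Nm * Pm)
  fold[Nm * Pm <= 1] <- Inf
  fold[masked] <- NA_real_
  dimnames(fold) <- dimnames(masked) <- list(N = signif(N, 6), pg = signif(pg, 6))
  structure(list(fold = fold, masked = masked, N = N, pg = pg),
            class = "cost_surface")
}

#' @export
as.data.frame.cost_surface <- function(x, ...) {
  data.frame(N = rep(x$N, times = length(x$pg)),
             pg = rep(x$pg, each = length(x$N)),
             fold_reduction = as.vector(x$fold),
             masked = as.vector(x$masked))
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf("Fold-reduction surface: %d sizes x %d germ fractions (%d masked)\n",
              length(x$N), length(x$pg), sum(x$masked)))
  print(signif(x$fold, 3))
  invisible(x)
}

#' @rdname cost_surface
#' @param x a \code{cost_surface} object.
#' @param nlevels number of contour levels.
#' @param ... passed to [graphics::contour].
#' @export
plot.cost_surface <- function(x, nlevels = 8, ...) {
  graphics::contour(log10(x$N), x$pg, x$fold, nlevels = nlevels,
                    xlab = expression(log[10] ~ "cell number N"),
                    ylab = expression("germ fraction" ~ p[g]), ...)
  invisible(x)
}

#' @export
print.life_cycle <- function(x, ...) {
  n <- length(x$N)
  cat(sprintf("Life cycle%s:\n", if (n > 1) sprintf("s (%d)", n) else ""))
  df <- data.frame(N = x$N, pg = signif(x$pg, 4),
                   tau = development_time(x$N),
                   r = signif(growth_rate(x), 4),
                   cost = signif(specialization_cost(x), 4))
  df$fold <- ifelse(x$N * x$pg > 1, signif(log(x$N) / log(x$N * x$pg), 4), Inf)
  print(df, row.names = n > 1)
  invisible(x)
}
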