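#' Validate a species table of cell and germ counts
#'
#' A comparative record per species: the maximum reported cell number and
#' the gonidia (germ-cell) count, from which the germ fraction
#' pg = n_germ / n_cells is derived. Rows violating the invariants
#' (n_cells >= 2, 1 <= n_germ <= n_cells) are rejected and reported, not
#' silently dropped.
#'
#' @param df data frame with columns \code{name}, \code{n_cells},
#'   \code{n_germ}.
#' @return Object of class \code{"species_table"} (a data frame with the
#'   derived \code{pg} column); rejected rows, with reasons, in attribute
#'   \code{"rejected"}.
#' @export
species_table <- function(df) {
  need <- c("name", "n_cells", "n_germ")
  if (!all(need %in% names(df)))
    stop("species table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$n_cells <- suppressWarnings(as.numeric(df$n_cells))
  df$n_germ <- suppressWarnings(as.numeric(df$n_germ))
  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(df$n_cells) | is.na(df$n_germ), "non-numeric count")
  reason <- bad(df$n_cells < 2, "n_cells < 2")
  reason <- bad(df$n_germ < 1, "no germ cells")
  reason <- bad(df$n_germ > df$n_cells, "n_germ exceeds n_cells")
  rejected <- cbind(df[!is.na(reason), , drop = FALSE],
                    reason = reason[!is.na(reason)])
  keep <- df[is.na(reason), , drop = FALSE]
  if (anyDuplicated(keep$name))
    stop("duplicated species names", call. = FALSE)
  keep$pg <- keep$n_germ / keep$n_cells
  rownames(keep) <- NULL
  structure(keep, rejected = rejected,
            class = c("species_table", "data.frame"))
}

#' Read a species table from CSV
#'
#' @param path CSV file with header columns \code{name}, \code{n_cells},
#'   \code{n_germ}.
#' @return A validated [species_table]; invalid rows are reported in a
#'   warning and kept in attribute \code{"rejected"}.
#' @export
load_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- species_table(df)
  rej <- attr(out, "rejected")
  if (nrow(rej))
    warning(sprintf("rejected %d row(s): %s", nrow(rej),
                    paste(rej$name, "(", rej$reason, ")", collapse = "; ")),
            call. = FALSE)
  out
}

#' @export
print.species_table <- function(x, ...) {
  cat(sprintf("Species table: %d species (%d rejected on load)\n",
              nrow(x), nrow(attr(x, "rejected"))))
  NextMethod()
}

#' Fit the germ-fraction scaling exponent across species
#'
#' The central comparative analysis: regresses log10 germ fraction on
#' log10 cell number across species, both by ordinary least squares on the
#' raw species values and by phylogenetic independent contrasts on the
#' supplied tree, returning the scaling exponent b in pg proportional to
#' N^b with r^2 and p for each route.
#'
#' Undifferentiated species (pg = 1) are excluded by default, since the
#' scaling law concerns species with germ-soma differentiation. A clade
#' filter restricts the analysis to the clade spanned by the matching
#' species (most-recent-common-ancestor pruning), e.g. the genus Volvox.
#' Species absent from the tree are a hard error: silently dropping them
#' would silently change the comparative result.
#'
#' @param species a [species_table] (or data frame coercible to one).
#' @param tree an \code{ape::phylo} tree whose tip labels cover the
#'   species names.
#' @param clade optional clade filter: either a regular expression matched
#'   against species names (e.g. \code{"^Volvox"}) or a character vector
#'   of species names; the analysis is restricted to the clade spanned by
#'   the matches.
#' @param exclude_undifferentiated drop species with pg = 1 (default TRUE).
#' @return Object of class \code{"germ_scaling"}: list with elements
#'   \code{ols} and \code{pic} (both [fit_scaling] objects), the data
#'   used, and the pruned tree.
#' @examples
#' ds <- generate_volvocine_data(volvocine_config(seed = 1))
#' fit <- germ_scaling(ds$species, ds$tree)
#' coef(fit$pic)
#' @export
germ_scaling <- function(species, tree, clade = NULL,
                         exclude_undifferentiated = TRUE) {
  if (!inherits(species, "species_table")) species <- species_table(species)
  stopifnot(inherits(tree, "phylo"))

  if (!is.null(clade)) {
    hit <- if (length(clade) == 1L) grepl(clade, species$name)
           else species$name %in% clade
    if (sum(hit) < 2L) stop("clade filter matches fewer than 2 species",
                            call. = FALSE)
    mrca <- ape::getMRCA(tree, species$name[hit])
    sub <- ape::extract.clade(tree, mrca)
    species <- species[species$name %in% sub$tip.label, , drop = FALSE]
  }
  if (exclude_undifferentiated)
    species <- species[species$pg < 1, , drop = FALSE]
  if (nrow(species) < 4L)
    stop("fewer than 4 species after filtering", call. = FALSE)

  missing <- setdiff(species$name, tree$tip.label)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tree <- ape::keep.tip(tree, species$name)

  logN <- stats::setNames(log10(species$n_cells), species$name)
  logpg <- stats::setNames(log10(species$pg), species$name)
  ols <- fit_scaling(unname(logN[species$name]), unname(logpg[species$name]),
                     method = "ols")
  cx <- pic_contrasts(tree, logN)
  cy <- pic_contrasts(tree, logpg)
  pic <- fit_scaling(as.numeric(cx), as.numeric(cy), method = "pic")
  structure(list(ols = ols, pic = pic, species = species, tree = tree,
                 clade = clade),
            class = "germ_scaling")
}

#' @export
print.germ_scaling <- function(x, ...) {
  cat(sprintf("Germ-fraction scaling across %d species%s\n",
              nrow(x$species),
              if (is.null(x$clade)) ""
              else sprintf(" (clade: %s)", paste(x$clade, collapse = ","))))
  cat("  "); print(x$ols)
  cat("  "); print(x$pic)
  invisible(x)
}

#' @export
summary.germ_scaling <- function(object, ...) {
  print(object)
  cat("\nOLS fit:\n"); summary(object$ols)
  cat("\nPIC fit:\n"); summary(object$pic)
  invisible(object)
}

#' @export
coef.germ_scaling <- function(object, ...) {
  c(ols = unname(coef(object$ols)["slope"]),
    pic = unname(coef(object$pic)))
}

#' @export
plot.germ_scaling <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  plot(x$ols, main = "species values (OLS)", ...)
  plot(x$pic, main = "independent contrasts", ...)
  invisible(x)
}

#' Is the proportional cost roughly constant across species?
#'
#' Computes the specialization cost -ln(pg)/ln(N) for every species and
#' summarizes its spread. A scaling exponent near -1 on the log-log line
#' implies a roughly constant proportional cost across sizes; the
#' coefficient of variation of the cost, set against the spread of log10 N,
#' quantifies how constant. Reported, not thresholded.
#'
#' @param species a [species_table].
#' @return List with per-species \code{cost}, \code{mean}, \code{sd},
#'   \code{cv}, and \code{logN_range} (span of log10 cell number).
#' @export
constant_cost_check <- function(species) {
  if (!inherits(species, "species_table")) species <- species_table(species)
  cost <- specialization_cost(species$n_cells, species$pg)
  list(cost = stats::setNames(cost, species$name),
       mean = mean(cost),
       sd = if (length(cost) > 1) stats::sd(cost) else 0,
       cv = if (mean(cost) > 0 && length(cost) > 1)
         stats::sd(cost) / mean(cost) else 0,
       logN_range = diff(range(log10(species$n_cells))))
}
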