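# Population fingerprints, population adjustment, nearest-population
# classification and its leave-one-out evaluation.

#' Average member fingerprints into a population fingerprint
#'
#' A population fingerprint is the element-wise mean of the normalized
#' fingerprints of the population's members. Members may come from
#' slightly different panels of the same array family, as long as all
#' share L.
#'
#' @param members list of normalized `genofp` fingerprints (>= 1).
#' @param name population name.
#' @return A `genofp` with `state = "population"`, plus `population` and
#'   `n_members` metadata.
#' @export
population_fingerprint <- function(members, name) {
  if (length(members) == 0) stop("population must have at least one member")
  Ls <- vapply(members, function(f) f$L, numeric(1))
  if (length(unique(Ls)) != 1)
    stop("members have mixed L: ", paste(unique(Ls), collapse = ", "))
  states <- vapply(members, function(f) f$state, character(1))
  if (any(states != "normalized"))
    stop("population fingerprints are built from normalized fingerprints")
  values <- Reduce(`+`, lapply(members, function(f) f$values)) / length(members)
  fp <- new_fingerprint(values, "population",
                        n_snps = round(mean(vapply(members,
                                                   function(f) f$n_snps,
                                                   numeric(1)))))
  fp$population <- as.character(name)
  fp$n_members <- length(members)
  fp
}

#' Adjust an individual fingerprint for its population
#'
#' Subtracts a population fingerprint from an individual's normalized
#' fingerprint. Adjustment cancels the correlation shared by all members
#' of a population, so that after adjustment unrelated same-population
#' individuals are essentially uncorrelated and close relatives stand out.
#'
#' @param fp a normalized `genofp`.
#' @param pop a population `genofp` with the same L.
#' @return A `genofp` with `state = "adjusted"` and `adjusted_to` metadata.
#' @export
adjust_fingerprint <- function(fp, pop) {
  stopifnot(inherits(fp, "genofp"), inherits(pop, "genofp"))
  if (!identical(pop$state, "population"))
    stop("second argument must be a population fingerprint")
  if (!identical(fp$state, "normalized"))
    stop("adjustment applies to normalized fingerprints")
  if (fp$L != pop$L)
    stop("fingerprint L = ", fp$L, " does not match population L = ", pop$L)
  out <- new_fingerprint(fp$values - pop$values, "adjusted", fp$panel,
                         fp$n_snps, fp$id)
  out$adjusted_to <- pop$population
  out
}

#' Classify a fingerprint to its nearest population
#'
#' Compares a query fingerprint against every population fingerprint via
#' Spearman correlation and ranks populations by decreasing rho. The full
#' ranking supports top-k accuracy reporting. Ties are broken
#' alphabetically by population name and flagged.
#'
#' @param fp a normalized (or adjusted) `genofp`.
#' @param pops list of population `genofp` objects sharing L with `fp`.
#' @return List of class `genofp_class` with `id`, `ranking` (data frame
#'   `population`, `rho`, sorted by rho descending), `assigned` (top name)
#'   and `tie` (logical).
#' @export
classify_fingerprint <- function(fp, pops) {
  if (length(pops) == 0) stop("need at least one population fingerprint")
  names <- vapply(pops, function(p) p$population, character(1))
  rho <- vapply(pops, function(p) fp_compare(fp, p)$rho, numeric(1))
  ord <- order(-rho, names)
  ranking <- data.frame(population = names[ord], rho = rho[ord],
                        stringsAsFactors = FALSE)
  structure(list(id = fp$id, ranking = ranking,
                 assigned = ranking$population[1],
                 tie = sum(rho == max(rho)) > 1),
            class = "genofp_class")
}

#' @export
print.genofp_class <- function(x, ...) {
  cat("classification", if (!is.null(x$id)) paste0("of '", x$id, "'"),
      "-> ", x$assigned, if (x$tie) " (tie)", "\n")
  print(utils::head(x$ranking, 3))
  invisible(x)
}

#' Leave-one-out evaluation of nearest-population assignment
#'
#' For each labeled individual, its own population's fingerprint is
#' recomputed without it (by the exact mean downdate
#' `(mean * n - self) / (n - 1)`), the individual is classified against
#' all population fingerprints, and the rank of the true label recorded.
#' Queries are normalized (not population-adjusted) fingerprints, since a
#' query's population is unknown at classification time.
#'
#' @param fps named list of normalized `genofp` fingerprints.
#' @param labels named character vector mapping individual id to population
#'   name; every population must have at least 2 members.
#' @return List of class `genofp_loo`: `top1`, `top2`, `top3` (fractions of
#'   individuals whose true population ranks <= 1, 2, 3), `confusion`
#'   (table of true vs assigned), and `detail` (per-individual data frame
#'   with the true label's rank).
#' @export
evaluate_loo <- function(fps, labels) {
  ids <- names(fps)
  if (is.null(ids) || !all(ids %in% names(labels)))
    stop("every fingerprint needs a label")
  labels <- labels[ids]
  tab <- table(labels)
  if (any(tab < 2))
    stop("leave-one-out undefined for population(s) of size 1: ",
         paste(names(tab)[tab < 2], collapse = ", "))

  pops <- sort(unique(labels))
  sums <- list(); npop <- integer(0)
  for (p in pops) {
    member_vals <- lapply(fps[labels == p], function(f) f$values)
    sums[[p]] <- Reduce(`+`, member_vals)
    npop[p] <- length(member_vals)
  }
  make_popfp <- function(values, name, n) {
    fp <- new_fingerprint(values, "population")
    fp$population <- name; fp$n_members <- n
    fp
  }

  detail <- data.frame(id = ids, true = labels,
                       assigned = NA_character_, rank_true = NA_integer_,
                       stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    own <- labels[i]
    popfps <- lapply(pops, function(p) {
      if (p == own)
        make_popfp((sums[[p]] - fps[[i]]$values) / (npop[p] - 1), p,
                   npop[p] - 1L)
      else
        make_popfp(sums[[p]] / npop[p], p, npop[p])
    })
    cl <- classify_fingerprint(fps[[i]], popfps)
    detail$assigned[i] <- cl$assigned
    detail$rank_true[i] <- match(own, cl$ranking$population)
  }
  confusion <- table(true = factor(detail$true, levels = pops),
                     assigned = factor(detail$assigned, levels = pops))
  structure(list(top1 = mean(detail$rank_true <= 1),
                 top2 = mean(detail$rank_true <= 2),
                 top3 = mean(detail$rank_true <= 3),
                 confusion = confusion, detail = detail),
            class = "genofp_loo")
}

#' @export
print.genofp_loo <- function(x, ...) {
  cat(sprintf("leave-one-out accuracy: top1 %.3f  top2 %.3f  top3 %.3f\n",
              x$top1, x$top2, x$top3))
  invisible(x)
}

#' Write leave-one-out results to TSV
#'
#' Emits the confusion matrix followed by a `top1 top2 top3` summary line.
#' @param loo result of [evaluate_loo()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loo <- function(loo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cm <- as.matrix(loo$confusion)
  writeLines(paste(c("true\\assigned", colnames(cm)), collapse = "\t"), con)
  for (r in rownames(cm))
    writeLines(paste(c(r, cm[r, ]), collapse = "\t"), con)
  writeLines(sprintf("top1\ttop2\ttop3"), con)
  writeLines(sprintf("%.6f\t%.6f\t%.6f", loo$top1, loo$top2, loo$top3), con)
  invisible(path)
}
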