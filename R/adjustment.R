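#' Specify a biasing pathway
#'
#' A biasing pathway carries the variant's effect to the outcome through a
#' confounder phenotype: its contribution to the crude variant-outcome
#' association is the product of the variant-confounder association `b_gc`
#' (from a GWAS of the confounder) and the confounder-outcome causal effect
#' `b_co` (from an MR analysis of the confounder on the outcome).
#'
#' @param b_gc variant-confounder association, confounder units per effect
#'   allele.
#' @param se_gc its standard error, positive.
#' @param b_co confounder-outcome causal estimate, outcome units per
#'   confounder unit.
#' @param se_co its standard error, positive.
#' @param label free-text label used in reports.
#' @return an object of class `pathway_spec`.
#' @examples
#' pathway_spec(b_gc = 0.2, se_gc = 0.02, b_co = 1.0, se_co = 0.1)
#' @export
pathway_spec <- function(b_gc, se_gc, b_co, se_co, label = "") {
  for (v in list(b_gc = b_gc, se_gc = se_gc, b_co = b_co, se_co = se_co)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_input("pathway components must be finite numeric scalars")
  }
  if (se_gc < 0 || se_co < 0) stop_input("pathway SEs must be non-negative")
  structure(list(b_gc = b_gc, se_gc = se_gc, b_co = b_co, se_co = se_co,
                 label = as.character(label)),
            class = "pathway_spec")
}

# delta-method variance of the product b_gc * b_co of two independent
# normally distributed estimates; exact (includes the se^2 * se^2 term)
# unless first_order = TRUE. Vectorized over all arguments.
product_variance <- function(b_gc, se_gc, b_co, se_co, first_order = FALSE) {
  v <- b_gc^2 * se_co^2 + b_co^2 * se_gc^2
  if (!first_order) v <- v + se_gc^2 * se_co^2
  v
}

.as_pathway_list <- function(pathway) {
  if (inherits(pathway, "pathway_spec")) return(list(pathway))
  if (is.list(pathway) && length(pathway) > 0L &&
      all(vapply(pathway, inherits, logical(1), "pathway_spec")))
    return(pathway)
  stop_input("'pathway' must be a pathway_spec or a non-empty list of them")
}

#' Adjust a variant-outcome association for a biasing pathway
#'
#' The two-step cis-MR adjustment: the estimated effect transmitted through
#' the confounder, `b_gc * b_co`, is subtracted from the crude variant-outcome
#' association, and the standard error is updated by propagation of error,
#' treating the three estimates as mutually independent:
#' \deqn{se_{adj}^2 = se_{go}^2 + b_{gc}^2 se_{co}^2 + b_{co}^2 se_{gc}^2 +
#'   se_{gc}^2 se_{co}^2}
#' This is the exact variance of a difference involving a product of two
#' independent normals, not the first-order approximation (which drops the
#' final cross term; set `first_order = TRUE` to compare). Adjustment can
#' only add uncertainty: the adjusted SE is never below the input SE.
#'
#' @param b_go crude variant-outcome association.
#' @param se_go its standard error, positive.
#' @param pathway a [pathway_spec()], or a list of them for sequential
#'   adjustment (see [sequential_adjust()]).
#' @param first_order drop the `se_gc^2 * se_co^2` term from the propagated
#'   variance. Default `FALSE`.
#' @return an object of class `tscmr_adjustment` with components `b_adj`,
#'   `se_pe`, `se_bs` (`NA` until [bootstrap_se()] is used), `subtracted`
#'   (the per-pathway products), `pathways`, `n_boot`, `seed`.
#' @examples
#' adjust_association(0.5, 0.1, pathway_spec(0.2, 0.02, 1.0, 0.1))
#' @seealso [bootstrap_se()], [sequential_adjust()], [adjust_table()]
#' @export
adjust_association <- function(b_go, se_go, pathway, first_order = FALSE) {
  if (!is.numeric(b_go) || length(b_go) != 1L || !is.finite(b_go))
    stop_input("b_go must be a finite numeric scalar")
  if (!is.numeric(se_go) || length(se_go) != 1L || !is.finite(se_go) ||
      se_go <= 0)
    stop_input("se_go must be a positive scalar")
  pw <- .as_pathway_list(pathway)
  subtracted <- vapply(pw, function(p) p$b_gc * p$b_co, numeric(1))
  var_add <- vapply(pw, function(p)
    product_variance(p$b_gc, p$se_gc, p$b_co, p$se_co, first_order),
    numeric(1))
  structure(list(b_adj = b_go - sum(subtracted),
                 se_pe = sqrt(se_go^2 + sum(var_add)),
                 se_bs = NA_real_,
                 subtracted = subtracted,
                 b_go = b_go, se_go = se_go,
                 pathways = pw,
                 first_order = first_order,
                 n_boot = NA_integer_, seed = NA_integer_),
            class = "tscmr_adjustment")
}

#' Sequentially adjust for several biasing pathways
#'
#' Subtracts each pathway's product in turn; point adjustments and propagated
#' variances both accumulate additively, so the result does not depend on the
#' order of the pathways. Validity requires the pathways to be mutually
#' independent: if one confounder is causally upstream of another, part of the
#' shared path is subtracted twice and the result over-adjusts (a warning is
#' emitted unconditionally as a reminder).
#'
#' @inheritParams adjust_association
#' @param pathways non-empty list of [pathway_spec()] objects.
#' @return a `tscmr_adjustment`, as [adjust_association()].
#' @export
sequential_adjust <- function(b_go, se_go, pathways, first_order = FALSE) {
  if (!is.list(pathways) || length(pathways) == 0L)
    stop_input("'pathways' must be a non-empty list of pathway_spec objects")
  warning("sequential adjustment is only valid when the biasing pathways ",
          "are mutually independent", call. = FALSE)
  adjust_association(b_go, se_go, pathways, first_order = first_order)
}

# vectorized parametric bootstrap kernel shared by bootstrap_se() and the
# simulation engine; returns the SD over n_boot draws of
# b_go* - sum_k b_gc_k* b_co_k*
boot_sd <- function(b_go, se_go, pw, n_boot) {
  draws <- stats::rnorm(n_boot, b_go, se_go)
  for (p in pw) {
    draws <- draws - stats::rnorm(n_boot, p$b_gc, p$se_gc) *
                     stats::rnorm(n_boot, p$b_co, p$se_co)
  }
  stats::sd(draws)
}

#' Bootstrap standard error of the adjusted association
#'
#' Parametric bootstrap alternative to the propagation-of-error SE: the three
#' (or more) estimates entering the adjustment are redrawn independently from
#' normal distributions centred on their estimates with their standard errors
#' as SDs, the adjusted association recomputed each time, and the sample SD
#' over `n_boot` replicates reported. In the summary-data setting this is the
#' only bootstrap available; as the propagated variance is exact for a product
#' of independent normals, the two SEs converge as `n_boot` grows.
#'
#' @inheritParams adjust_association
#' @param n_boot number of bootstrap replicates, at least 100. Default 10000.
#' @param seed integer seed; the result is reproducible given the seed. The
#'   RNG state of the session is left untouched.
#' @return a `tscmr_adjustment` with `se_bs`, `n_boot` and `seed` filled in.
#' @examples
#' bootstrap_se(0.5, 0.1, pathway_spec(0.2, 0.02, 1.0, 0.1), seed = 1)
#' @export
bootstrap_se <- function(b_go, se_go, pathway, n_boot = 10000L, seed = 1L,
                         first_order = FALSE) {
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 100)
    stop_input("n_boot must be at least 100")
  out <- adjust_association(b_go, se_go, pathway, first_order = first_order)
  out$se_bs <- with_seed(seed, boot_sd(b_go, se_go, out$pathways, n_boot))
  out$n_boot <- as.integer(n_boot)
  out$seed <- as.integer(seed)
  out
}

# evaluate `expr` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Adjust a table of harmonized variant-outcome associations
#'
#' Vectorizes [adjust_association()] over the instruments of a harmonized
#' exposure-outcome table: each variant's outcome association is adjusted
#' using its own variant-confounder association and a single confounder-
#' outcome MR estimate shared across variants. Instruments missing from the
#' confounder table are excluded with a warning (a missing confounder
#' association is not evidence of a zero one).
#'
#' @param records a `data.frame` with columns `snp_id`, `beta_out`, `se_out`
#'   (crude variant-outcome associations, e.g. the `beta_other`/`se_other`
#'   columns of a [harmonize()] result restricted to retained rows).
#' @param confounder a `data.frame` with columns `snp_id`, `beta`, `se`:
#'   per-variant confounder associations aligned to the same effect alleles.
#' @param b_co,se_co confounder-outcome MR estimate and its SE.
#' @param n_boot bootstrap replicates per variant (0 to skip the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @param first_order see [adjust_association()].
#' @return a `data.frame` keyed by `snp_id`, input order preserved:
#'   `beta_adj`, `se_pe`, `se_bs`, `subtracted_path`.
#' @export
adjust_table <- function(records, confounder, b_co, se_co,
                         n_boot = 10000L, seed = 1L, first_order = FALSE) {
  needed <- c("snp_id", "beta_out", "se_out")
  if (!all(needed %in% names(records)))
    stop_input("'records' needs columns ", paste(needed, collapse = ", "))
  if (!all(c("snp_id", "beta", "se") %in% names(confounder)))
    stop_input("'confounder' needs columns snp_id, beta, se")
  idx <- match(records$snp_id, confounder$snp_id)
  missing <- is.na(idx)
  if (any(missing)) {
    warning("excluded ", sum(missing), " instrument(s) absent from the ",
            "confounder table: ",
            paste(records$snp_id[missing], collapse = ", "), call. = FALSE)
  }
  kept <- which(!missing)
  if (length(kept) == 0L) stop_input("no instruments left after matching")
  res <- vector("list", length(kept))
  for (j in seq_along(kept)) {
    i <- kept[j]
    pw <- pathway_spec(confounder$beta[idx[i]], confounder$se[idx[i]],
                       b_co, se_co)
    a <- if (n_boot > 0)
      bootstrap_se(records$beta_out[i], records$se_out[i], pw,
                   n_boot = n_boot, seed = seed + j, first_order = first_order)
    else adjust_association(records$beta_out[i], records$se_out[i], pw,
                            first_order = first_order)
    res[[j]] <- data.frame(snp_id = records$snp_id[i],
                           beta_adj = a$b_adj, se_pe = a$se_pe,
                           se_bs = a$se_bs,
                           subtracted_path = sum(a$subtracted),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
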