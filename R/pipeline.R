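#' Pipeline configuration
#'
#' Collects every input and tuning choice of the end-to-end workflow:
#' instrument selection, harmonization, the crude cis-MR, one confounder-
#' outcome MR per biasing pathway, the two-step adjustment of the
#' variant-outcome associations, and the adjusted cis-MR.
#'
#' @param exposure_path,outcome_path GWAS summary-statistic files
#'   (see [read_summary_stats()]).
#' @param confounder_paths character vector (optionally named by confounder
#'   label) of confounder GWAS files; at least one.
#' @param exposure_map,outcome_map,confounder_maps optional column maps per
#'   file (`confounder_maps`: a list parallel to `confounder_paths`).
#' @param instruments optional explicit character vector of variant ids to
#'   use as cis instruments (e.g. a pre-clumped list); if `NULL`, variants
#'   passing `p_threshold` in the exposure GWAS are used.
#' @param p_threshold exposure instrument p-value threshold. Default 5e-8.
#' @param confounder_p_threshold instrument threshold for each confounder-
#'   outcome MR. Default 5e-8.
#' @param q_pvalue_threshold heterogeneity p-value below which the weighted
#'   median replaces IVW as the primary estimator. Default 0.05.
#' @param palindrome_eaf_window see [harmonize()]. Default 0.08.
#' @param n_boot bootstrap replicates for adjusted-association SEs.
#' @param seed integer seed for every stochastic step.
#' @param out_dir output directory for the report bundle; created if absent.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(exposure_path, outcome_path, confounder_paths,
                            exposure_map = NULL, outcome_map = NULL,
                            confounder_maps = NULL,
                            instruments = NULL,
                            p_threshold = 5e-8,
                            confounder_p_threshold = 5e-8,
                            q_pvalue_threshold = 0.05,
                            palindrome_eaf_window = 0.08,
                            n_boot = 10000L, seed = 1L,
                            out_dir = tempfile("tscmr_run_")) {
  if (length(confounder_paths) < 1L)
    stop_config("at least one confounder GWAS is required")
  if (q_pvalue_threshold <= 0 || q_pvalue_threshold >= 1)
    stop_config("q_pvalue_threshold must be in (0, 1)")
  labels <- names(confounder_paths) %||%
    paste0("confounder", seq_along(confounder_paths))
  labels[labels == ""] <- paste0("confounder", which(labels == ""))
  structure(list(exposure_path = exposure_path, outcome_path = outcome_path,
                 confounder_paths = stats::setNames(as.character(confounder_paths),
                                                    labels),
                 exposure_map = exposure_map, outcome_map = outcome_map,
                 confounder_maps = confounder_maps,
                 instruments = instruments,
                 p_threshold = p_threshold,
                 confounder_p_threshold = confounder_p_threshold,
                 q_pvalue_threshold = q_pvalue_threshold,
                 palindrome_eaf_window = palindrome_eaf_window,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the arguments of [pipeline_config()]; a JSON schema of
#' the file format ships with the package
#' (`system.file("schema", "pipeline-config.json", package = "tscmr")`).
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L)
    stop_config("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (f in c("exposure_path", "outcome_path", "confounder_paths")) {
    if (is.null(y[[f]])) stop_config("config field '", f, "' is required")
  }
  if (!is.null(y$confounder_paths) && is.list(y$confounder_paths))
    y$confounder_paths <- unlist(y$confounder_paths)
  do.call(pipeline_config, y)
}

# build the spec'd estimator results table from an mr_fit
#' @export
as.data.frame.mr_fit <- function(x, ...) {
  rows <- lapply(x$estimates, function(e) {
    data.frame(method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high,
               n_snps = e$n_snps,
               Q = x$Q$Q %||% NA_real_, Q_p = x$Q$p %||% NA_real_,
               intercept = e$intercept, intercept_se = e$intercept_se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent deflation of the adjusted relative to the crude estimate
#'
#' `100 * (crude - adjusted) / crude`: the share of the crude pooled estimate
#' that the pathway adjustment removed. Undefined (NA) for a zero crude
#' estimate.
#'
#' @param crude,adjusted pooled causal estimates.
#' @return percentage (vectorized).
#' @export
percent_difference <- function(crude, adjusted) {
  out <- 100 * (crude - adjusted) / crude
  out[crude == 0] <- NA_real_
  out
}

#' Run the end-to-end two-step cis-MR workflow
#'
#' Reads the exposure, outcome and confounder GWAS tables; selects and
#' harmonizes instruments; fits the crude cis-MR; fits one confounder-outcome
#' MR per confounder (primary estimator chosen by the heterogeneity rule);
#' adjusts the variant-outcome associations for every pathway; fits the
#' adjusted cis-MR; and writes a report bundle (per-variant and pooled TSVs,
#' a plain-text report, and a decision log) to `config$out_dir`. Output files
#' contain no timestamps, so rerunning with the same config and seed
#' reproduces them byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `tscmr_pipeline` (invisible components:
#'   `crude_fit`, `confounder_fits`, `adjustment`, `adjusted_fit`,
#'   `percent_difference`, `f_stats`, `accounting`, `files`, `log`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  logenv <- new.env()
  logenv$lines <- character()
  log_ <- function(level, ...) {
    logenv$lines <- c(logenv$lines, paste0("[", level, "] ", paste0(...)))
  }

  exposure <- read_summary_stats(config$exposure_path, config$exposure_map)
  outcome <- read_summary_stats(config$outcome_path, config$outcome_map)
  log_("INFO", "read exposure (", nrow(exposure), " rows), outcome (",
       nrow(outcome), " rows)")

  # --- cis instrument selection -------------------------------------------
  if (!is.null(config$instruments)) {
    instruments <- exposure[exposure$snp_id %in% config$instruments, ,
                            drop = FALSE]
    absent <- setdiff(config$instruments, exposure$snp_id)
    if (length(absent) > 0L)
      log_("WARN", "instrument(s) absent from exposure GWAS: ",
           paste(absent, collapse = ", "))
  } else {
    instruments <- filter_instruments(exposure, config$p_threshold)
    log_("INFO", nrow(instruments), " instrument(s) pass p < ",
         format(config$p_threshold))
  }
  if (nrow(instruments) == 0L) stop_input("no usable exposure instruments")
  accounting <- data.frame(snp_id = instruments$snp_id, status = "used",
                           reason = "", stringsAsFactors = FALSE)
  account <- function(ids, status, reason) {
    i <- match(ids, accounting$snp_id)
    accounting$status[i] <<- status
    accounting$reason[i] <<- reason
  }

  # --- harmonize exposure/outcome and fit the crude cis-MR ----------------
  h_out <- harmonize(instruments, outcome, config$palindrome_eaf_window)
  for (a in c("dropped_palindromic", "dropped_incompatible")) {
    bad <- h_out$snp_id[h_out$action == a]
    if (length(bad) > 0L) {
      account(bad, "dropped", a)
      log_("WARN", a, " during exposure/outcome harmonization: ",
           paste(bad, collapse = ", "))
    }
  }
  lost <- setdiff(instruments$snp_id, h_out$snp_id)
  if (length(lost) > 0L) {
    account(lost, "excluded", "absent from outcome GWAS")
    log_("WARN", "absent from outcome GWAS: ", paste(lost, collapse = ", "))
  }
  flipped <- h_out$snp_id[h_out$action == "flipped"]
  if (length(flipped) > 0L)
    log_("INFO", "flipped to exposure effect allele: ",
         paste(flipped, collapse = ", "))
  h_use <- h_out[h_out$action %in% c("kept", "flipped"), , drop = FALSE]
  if (nrow(h_use) == 0L) stop_input("all instruments excluded during ",
                                    "exposure/outcome harmonization")
  rs_crude <- ratio_input(h_use$beta_base, h_use$se_base,
                          h_use$beta_other, h_use$se_other, h_use$snp_id)
  crude_fit <- mr_fit(rs_crude, config$q_pvalue_threshold,
                      seed = config$seed)
  log_("INFO", "crude cis-MR primary estimator: ", crude_fit$primary)

  f_stats <- data.frame(snp_id = h_use$snp_id,
                        f_stat = f_statistic(h_use$beta_base, h_use$se_base))

  # --- one confounder-outcome MR per pathway, then adjust -----------------
  confounder_fits <- list()
  adj_records <- data.frame(snp_id = h_use$snp_id,
                            beta_out = h_use$beta_other,
                            se_out = h_use$se_other,
                            stringsAsFactors = FALSE)
  adjustment <- NULL
  for (ci in seq_along(config$confounder_paths)) {
    label <- names(config$confounder_paths)[ci]
    conf <- read_summary_stats(config$confounder_paths[[ci]],
                               config$confounder_maps[[ci]])
    conf_inst <- filter_instruments(conf, config$confounder_p_threshold)
    if (nrow(conf_inst) < 1L)
      stop_input("no instruments for confounder '", label, "'")
    h_conf_out <- harmonize(conf_inst, outcome, config$palindrome_eaf_window)
    h_co <- h_conf_out[h_conf_out$action %in% c("kept", "flipped"), ,
                       drop = FALSE]
    log_("INFO", "confounder '", label, "': ", nrow(h_co),
         " instrument(s) harmonized to outcome")
    rs_conf <- ratio_input(h_co$beta_base, h_co$se_base,
                           h_co$beta_other, h_co$se_other, h_co$snp_id)
    cfit <- mr_fit(rs_conf, config$q_pvalue_threshold,
                   seed = config$seed + ci)
    log_("INFO", "confounder '", label, "' primary estimator: ",
         cfit$primary,
         if (!is.na(cfit$Q$p)) paste0(" (Q p = ", signif(cfit$Q$p, 3), ")"))
    confounder_fits[[label]] <- cfit
    primary <- cfit$estimates[[cfit$primary]]

    # per-cis-variant confounder associations, aligned to exposure alleles
    h_cis_conf <- harmonize(instruments[instruments$snp_id %in%
                                          adj_records$snp_id, , drop = FALSE],
                            conf, config$palindrome_eaf_window)
    h_cc <- h_cis_conf[h_cis_conf$action %in% c("kept", "flipped"), ,
                       drop = FALSE]
    conf_table <- data.frame(snp_id = h_cc$snp_id, beta = h_cc$beta_other,
                             se = h_cc$se_other, stringsAsFactors = FALSE)
    step <- withCallingHandlers(
      adjust_table(adj_records, conf_table,
                   b_co = primary$beta, se_co = primary$se,
                   n_boot = config$n_boot, seed = config$seed + 100L * ci),
      warning = function(w) {
        log_("WARN", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    gone <- setdiff(adj_records$snp_id, step$snp_id)
    if (length(gone) > 0L)
      account(gone, "excluded",
              paste0("absent from confounder '", label, "' GWAS"))
    # accumulate: the adjusted association becomes the outcome input of the
    # next pathway; PE variance accumulates additively
    prev <- adj_records[match(step$snp_id, adj_records$snp_id), ]
    sub_prev <- if (is.null(adjustment)) 0 else
      adjustment$subtracted_path[match(step$snp_id, adjustment$snp_id)]
    adjustment <- data.frame(snp_id = step$snp_id,
                             beta_adj = step$beta_adj,
                             se_pe = step$se_pe, se_bs = step$se_bs,
                             subtracted_path = step$subtracted_path + sub_prev,
                             stringsAsFactors = FALSE)
    adj_records <- data.frame(snp_id = step$snp_id, beta_out = step$beta_adj,
                              se_out = step$se_pe, stringsAsFactors = FALSE)
  }
  if (length(confounder_fits) > 1L)
    log_("WARN", "sequential adjustment over multiple pathways assumes the ",
         "pathways are mutually independent")

  # --- adjusted cis-MR and comparison -------------------------------------
  keep <- match(adjustment$snp_id, h_use$snp_id)
  rs_adj <- ratio_input(h_use$beta_base[keep], h_use$se_base[keep],
                        adjustment$beta_adj, adjustment$se_pe,
                        adjustment$snp_id)
  adjusted_fit <- mr_fit(rs_adj, config$q_pvalue_threshold,
                         seed = config$seed + 1L)

  # compare crude and adjusted with the same estimator (the crude primary)
  cmp_method <- if (crude_fit$primary %in% names(adjusted_fit$estimates))
    crude_fit$primary else adjusted_fit$primary
  pdiff <- percent_difference(crude_fit$estimates[[cmp_method]]$beta,
                              adjusted_fit$estimates[[cmp_method]]$beta)
  log_("INFO", "percent difference (", cmp_method, "): ",
       round(pdiff), "%")

  out <- structure(list(config = config,
                        crude_fit = crude_fit,
                        confounder_fits = confounder_fits,
                        adjustment = adjustment,
                        adjusted_fit = adjusted_fit,
                        percent_difference = pdiff,
                        comparison_method = cmp_method,
                        f_stats = f_stats,
                        harmonized = h_out,
                        accounting = accounting,
                        log = logenv$lines),
                   class = "tscmr_pipeline")
  out$files <- .write_bundle(out, config$out_dir)
  out
}

# write the report bundle; deterministic content only
.write_bundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  tsv <- function(d, f) {
    utils::write.table(d, path(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path(f)
  }
  files <- c(
    harmonized = tsv(x$harmonized, "harmonized.tsv"),
    crude_per_snp = tsv(cbind(x$crude_fit$data,
                              ratio = x$crude_fit$data$b_gy /
                                x$crude_fit$data$b_gx),
                        "crude_per_snp.tsv"),
    crude_estimates = tsv(as.data.frame(x$crude_fit), "crude_estimates.tsv"),
    adjusted_per_snp = tsv(x$adjustment, "adjusted_per_snp.tsv"),
    adjusted_estimates = tsv(as.data.frame(x$adjusted_fit),
                             "adjusted_estimates.tsv"),
    f_statistics = tsv(x$f_stats, "f_statistics.tsv"),
    accounting = tsv(x$accounting, "instrument_accounting.tsv"))
  for (label in names(x$confounder_fits)) {
    files[paste0("confounder_", label)] <-
      tsv(as.data.frame(x$confounder_fits[[label]]),
          paste0("confounder_mr_", label, ".tsv"))
  }
  rep_lines <- c(
    "two-step cis-MR report",
    "======================",
    "",
    paste0("instruments used: ",
           sum(x$accounting$status == "used"), " of ",
           nrow(x$accounting)),
    paste0("crude primary (", x$crude_fit$primary, "): ",
           sprintf("%.6g [%.6g, %.6g]",
                   x$crude_fit$estimates[[x$crude_fit$primary]]$beta,
                   x$crude_fit$estimates[[x$crude_fit$primary]]$ci_low,
                   x$crude_fit$estimates[[x$crude_fit$primary]]$ci_high)),
    paste0("adjusted primary (", x$adjusted_fit$primary, "): ",
           sprintf("%.6g [%.6g, %.6g]",
                   x$adjusted_fit$estimates[[x$adjusted_fit$primary]]$beta,
                   x$adjusted_fit$estimates[[x$adjusted_fit$primary]]$ci_low,
                   x$adjusted_fit$estimates[[x$adjusted_fit$primary]]$ci_high)),
    paste0("percent difference (", x$comparison_method, "): ",
           ifelse(is.na(x$percent_difference), "NA",
                  paste0(round(x$percent_difference), "%"))),
    "",
    "instrument accounting:",
    paste0("  ", x$accounting$snp_id, ": ", x$accounting$status,
           ifelse(x$accounting$reason == "", "",
                  paste0(" (", x$accounting$reason, ")"))))
  writeLines(rep_lines, path("report.txt"))
  files["report"] <- path("report.txt")
  writeLines(x$log, path("pipeline_log.txt"))
  files["log"] <- path("pipeline_log.txt")
  files
}
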