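# shared fixture builders; everything is generated in code at test time

std_header <- c("SNP", "effect_allele", "other_allele", "eaf", "beta", "se",
                "pval", "samplesize")

write_gwas <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

gwas_row <- function(snp, ea, oa, eaf, beta, se,
                     pval = 2 * pnorm(-abs(beta / se)), n = 100000) {
  data.frame(snp_id = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

# a random set of per-variant associations for estimator tests
random_ratios <- function(n, seed, theta = 1.5) {
  set.seed(seed)
  b_gx <- runif(n, 0.05, 0.3) * sample(c(-1, 1), n, replace = TRUE)
  se_gx <- runif(n, 0.005, 0.02)
  b_gy <- theta * b_gx + rnorm(n, 0, 0.02)
  se_gy <- runif(n, 0.01, 0.05)
  ratio_input(b_gx, se_gx, b_gy, se_gy)
}

# GWAS file triple with known truth for pipeline tests:
# exposure -> outcome effect `theta`, confounder -> outcome effect `b_co`,
# `n_cis` cis instruments carrying confounder associations `b_gc_cis`,
# `n_conf` genome-wide confounder instruments.
make_gwas_triple <- function(theta = 0.5, b_co = 0.3,
                             b_gc_cis = c(0.05, 0.02, -0.03),
                             n_conf = 6, seed = 1, noise = 0.002) {
  set.seed(seed)
  n_cis <- length(b_gc_cis)
  cis_id <- paste0("cis", seq_len(n_cis))
  conf_id <- paste0("conf", seq_len(n_conf))
  b_gx <- seq(0.12, 0.08, length.out = n_cis)
  b_gc_inst <- runif(n_conf, 0.08, 0.15)
  alle <- list(c("A", "G"), c("C", "T"), c("G", "C"), c("T", "G"),
               c("A", "C"), c("C", "A"), c("G", "T"), c("T", "C"))
  al <- function(i) alle[[(i - 1L) %% length(alle) + 1L]]
  rows <- function(ids, betas, se, eafs) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      a <- al(i)
      gwas_row(ids[i], a[1], a[2], eafs[i], betas[i], se)
    }))
  }
  eaf_cis <- seq(0.2, 0.4, length.out = n_cis)
  eaf_conf <- seq(0.25, 0.7, length.out = n_conf)
  exposure <- rbind(
    rows(cis_id, b_gx + rnorm(n_cis, 0, noise), 0.01, eaf_cis),
    rows(conf_id, rnorm(n_conf, 0, noise), 0.01, eaf_conf))
  outcome <- rbind(
    rows(cis_id, theta * b_gx + b_co * b_gc_cis + rnorm(n_cis, 0, noise),
         0.015, eaf_cis),
    rows(conf_id, b_co * b_gc_inst + rnorm(n_conf, 0, noise), 0.015,
         eaf_conf))
  confounder <- rbind(
    rows(cis_id, b_gc_cis + rnorm(n_cis, 0, noise), 0.008, eaf_cis),
    rows(conf_id, b_gc_inst + rnorm(n_conf, 0, noise), 0.008, eaf_conf))
  list(exposure = write_gwas(exposure), outcome = write_gwas(outcome),
       confounder = write_gwas(confounder),
       truth = list(theta = theta, b_co = b_co, b_gx = b_gx,
                    b_gc_cis = b_gc_cis, cis_id = cis_id))
}

quiet_pipeline <- function(cfg) {
  suppressWarnings(suppressMessages(run_pipeline(cfg)))
}
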