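#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a TSV or CSV table of per-variant association statistics into the
#' standard layout used throughout the package: `snp_id`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`. The effect estimate
#' `beta` always refers to `effect_allele`. Common GWAS header spellings
#' (e.g. `SNP`, `A1`/`A2`, `samplesize`) are recognised automatically; any
#' other layout can be declared through `column_map`.
#'
#' Rows violating the basic invariants (missing beta, non-positive SE,
#' invalid or identical alleles, allele-frequency outside \[0, 1\]) are
#' skipped, with the row index and reason recorded in the `"skipped"`
#' attribute of the result.
#'
#' @param path path to a delimited text file with a header row. Files ending
#'   in `.csv` are read as comma-separated, anything else as tab-separated.
#' @param column_map optional named character vector mapping columns of the
#'   file to standard fields, e.g. `c(effect_size = "beta", rsID = "snp_id")`.
#'   Fields not mentioned are matched against the built-in aliases.
#' @return a `data.frame` (class `summary_assoc`) with the standard columns,
#'   one row per valid input row, input order preserved. Attribute `skipped`
#'   holds a `data.frame` of skipped rows and reasons.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("SNP\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tN",
#'              "rs1\tA\tG\t0.30\t0.10\t0.01\t1e-20\t50000"), tsv)
#' read_summary_stats(tsv)
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  std <- .standardize_columns(raw, column_map)

  n_in <- nrow(std)
  reason <- character(n_in)
  allele_ok <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  std$effect_allele <- toupper(as.character(std$effect_allele))
  std$other_allele <- toupper(as.character(std$other_allele))

  bad <- is.na(std$beta)
  reason[bad & reason == ""] <- "missing beta"
  bad2 <- is.na(std$se) | std$se <= 0
  reason[bad2 & reason == ""] <- "nonpositive SE"
  bad3 <- !allele_ok(std$effect_allele) | !allele_ok(std$other_allele)
  reason[bad3 & reason == ""] <- "invalid alleles"
  bad4 <- !bad3 & std$effect_allele == std$other_allele
  reason[bad4 & reason == ""] <- "identical alleles"
  bad5 <- !is.na(std$eaf) & (std$eaf < 0 | std$eaf > 1)
  reason[bad5 & reason == ""] <- "EAF outside [0,1]"
  std$pval[!is.na(std$pval) & (std$pval <= 0 | std$pval > 1)] <- NA_real_
  std$n[!is.na(std$n) & std$n <= 0] <- NA_real_

  keep <- reason == ""
  skipped <- data.frame(row = which(!keep),
                        snp_id = std$snp_id[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- std[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop_input("no parseable rows in ", path)
  if (nrow(skipped) > 0L) {
    message(nrow(skipped), " row(s) skipped while reading ", basename(path),
            ": ", paste(unique(skipped$reason), collapse = ", "))
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("summary_assoc", "data.frame")
  out
}

# map raw column names onto the standard fields; error on missing mandatory ones
.standardize_columns <- function(raw, column_map) {
  aliases <- list(
    snp_id = c("snp_id", "snp", "rsid", "id", "variant", "markername"),
    effect_allele = c("effect_allele", "ea", "a1", "alt"),
    other_allele = c("other_allele", "oa", "a2", "nea", "ref"),
    eaf = c("eaf", "effect_allele_frequency", "af", "freq"),
    beta = c("beta", "b", "effect"),
    se = c("se", "stderr", "standard_error", "sebeta"),
    pval = c("pval", "p", "pvalue", "p_value"),
    n = c("n", "samplesize", "sample_size", "ntotal")
  )
  nms <- names(raw)
  lower <- tolower(nms)
  resolved <- stats::setNames(rep(NA_character_, length(aliases)), names(aliases))
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(unname(column_map), names(aliases))
    if (length(unknown) > 0L)
      stop_config("column_map targets unknown field(s): ",
                  paste(unknown, collapse = ", "))
    missing_src <- setdiff(names(column_map), nms)
    if (length(missing_src) > 0L)
      stop_config("column_map names column(s) absent from the file: ",
                  paste(missing_src, collapse = ", "))
    resolved[unname(column_map)] <- names(column_map)
  }
  for (field in names(aliases)) {
    if (!is.na(resolved[[field]])) next
    hit <- which(lower %in% aliases[[field]])
    if (length(hit) > 0L) resolved[[field]] <- nms[hit[1L]]
  }
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  absent <- mandatory[is.na(resolved[mandatory])]
  if (length(absent) > 0L)
    stop_config("mandatory column(s) not found: ",
                paste(absent, collapse = ", "),
                " (use column_map to declare them)")
  out <- data.frame(snp_id = as.character(raw[[resolved[["snp_id"]]]]),
                    stringsAsFactors = FALSE)
  for (field in c("effect_allele", "other_allele")) {
    out[[field]] <- as.character(raw[[resolved[[field]]]])
  }
  for (field in c("eaf", "beta", "se", "pval", "n")) {
    out[[field]] <- if (is.na(resolved[[field]])) NA_real_
                    else suppressWarnings(as.numeric(raw[[resolved[[field]]]]))
  }
  out
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize two sets of summary associations to a common effect allele
#'
#' Aligns the `other` study's per-variant statistics to the effect allele of
#' the `base` study, the orientation step required before any two-sample MR
#' computation. Variants present in only one study are dropped; where the
#' `other` study reports the swapped allele pair, its `beta` is negated and
#' its `eaf` complemented; strand flips (A/T, C/G complements) are resolved
#' by complementing before aligning. Palindromic variants (A/T or G/C pairs),
#' whose strand cannot be inferred from the alleles, are resolved through the
#' allele frequencies and dropped whenever either study's EAF lies within
#' `palindrome_eaf_window` of 0.5 (or is missing).
#'
#' @param base,other `summary_assoc` tables (or data.frames with the standard
#'   columns), each keyed by unique `snp_id`.
#' @param palindrome_eaf_window half-width of the ambiguity window around an
#'   EAF of 0.5, in \[0, 0.5). Default 0.08.
#' @return a `data.frame` (class `harmonized`) with one row per shared
#'   variant, in `base` order: `snp_id`, `effect_allele`, `other_allele`
#'   (the base orientation), `beta_base`, `se_base`, `eaf_base`, `beta_other`,
#'   `se_other`, `eaf_other`, and `action` (one of `kept`, `flipped`,
#'   `dropped_palindromic`, `dropped_incompatible`). Dropped rows keep their
#'   unaligned statistics; downstream analyses should use rows with action
#'   `kept` or `flipped` only.
#' @export
harmonize <- function(base, other, palindrome_eaf_window = 0.08) {
  if (palindrome_eaf_window < 0 || palindrome_eaf_window >= 0.5)
    stop_input("palindrome_eaf_window must be in [0, 0.5)")
  for (nm in c("base", "other")) {
    ids <- get(nm)$snp_id
    if (anyDuplicated(ids))
      stop_input("duplicated snp_id in '", nm, "' table: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  common <- base$snp_id[base$snp_id %in% other$snp_id]
  b <- base[match(common, base$snp_id), , drop = FALSE]
  o <- other[match(common, other$snp_id), , drop = FALSE]

  n <- length(common)
  action <- character(n)
  beta_o <- o$beta
  eaf_o <- o$eaf

  comp <- function(a) unname(.COMPLEMENT[a])
  for (i in seq_len(n)) {
    be <- b$effect_allele[i]; bo <- b$other_allele[i]
    oe <- o$effect_allele[i]; oo <- o$other_allele[i]
    palindromic <- identical(comp(be), bo)
    if (palindromic) {
      if (!setequal(c(oe, oo), c(be, bo))) {
        action[i] <- "dropped_incompatible"
        next
      }
      ea_b <- b$eaf[i]; ea_o <- o$eaf[i]
      ambiguous <- function(f) is.na(f) ||
        abs(f - 0.5) < palindrome_eaf_window || f == 0.5
      if (ambiguous(ea_b) || ambiguous(ea_o)) {
        action[i] <- "dropped_palindromic"
        next
      }
      # allele labels carry no strand information for a palindromic pair:
      # orient purely by frequency (flip iff the EAFs fall on opposite
      # sides of 0.5; a label swap and a strand flip cancel)
      if (sign(ea_b - 0.5) == sign(ea_o - 0.5)) {
        action[i] <- "kept"
      } else {
        action[i] <- "flipped"
        beta_o[i] <- -beta_o[i]
        eaf_o[i] <- 1 - eaf_o[i]
      }
      next
    }
    if (identical(oe, be) && identical(oo, bo)) {
      action[i] <- "kept"
    } else if (identical(oe, bo) && identical(oo, be)) {
      action[i] <- "flipped"
      beta_o[i] <- -beta_o[i]
      eaf_o[i] <- 1 - eaf_o[i]
    } else if (identical(comp(oe), be) && identical(comp(oo), bo)) {
      action[i] <- "kept"        # other study reported the opposite strand
    } else if (identical(comp(oe), bo) && identical(comp(oo), be)) {
      action[i] <- "flipped"
      beta_o[i] <- -beta_o[i]
      eaf_o[i] <- 1 - eaf_o[i]
    } else {
      action[i] <- "dropped_incompatible"
    }
  }

  out <- data.frame(snp_id = common,
                    effect_allele = b$effect_allele,
                    other_allele = b$other_allele,
                    beta_base = b$beta, se_base = b$se, eaf_base = b$eaf,
                    beta_other = beta_o, se_other = o$se, eaf_other = eaf_o,
                    action = action,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("harmonized", "data.frame")
  out
}

#' Select genome-wide significant instruments
#'
#' Keeps associations whose p-value falls strictly below `p_threshold`
#' (default the conventional genome-wide significance level, 5e-8). Where a
#' row carries no p-value, a two-sided normal p-value is computed from
#' `beta`/`se`.
#'
#' @param assocs a `summary_assoc` table.
#' @param p_threshold significance threshold in (0, 1\].
#' @return the subset of `assocs` passing the threshold, input order
#'   preserved.
#' @export
filter_instruments <- function(assocs, p_threshold = 5e-8) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    stop_input("p_threshold must be in (0, 1]")
  p <- assocs$pval
  p[is.na(p)] <- z_pvalue(assocs$beta[is.na(p)], assocs$se[is.na(p)])
  out <- assocs[p < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    message("no instruments pass p < ", format(p_threshold))
  out
}

#' Write a harmonized table to TSV
#'
#' @param x a `harmonized` table from [harmonize()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
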