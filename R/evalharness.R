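# Evaluation against human-curated reference catalogs.
#
# A reference record is a (pmid, rsid, phenotype, p-value) tuple. Recovery
# keys on pmid + rsid + phenotype equivalence; phenotype equivalence is
# decided by string identity (after case folding and whitespace
# normalization) or by an externally curated mapping table whose entries
# are graded "exact" or "approximate" (e.g., "smoking behaviors" is an
# approximate match for "cigarette packs per day"). P-values are not
# required to match for recovery; an optional relative-tolerance check is
# available.

#' Read a reference catalog
#'
#' @param path TSV with columns `pmid`, `rsid`, `phenotype`, `p_value`
#'   (extra columns ignored; names matched case-insensitively, and
#'   GWAS-Catalog-style aliases `pubmedid`, `snps`, `disease_trait`,
#'   `p.value` are accepted).
#' @return A reference tibble.
#' @export
read_reference <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  alias <- c(pubmedid = "pmid", snps = "rsid", disease_trait = "phenotype",
             "p.value" = "p_value", pvalue = "p_value")
  for (a in names(alias)) {
    if (a %in% names(df) && !(alias[[a]] %in% names(df))) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  need <- c("pmid", "rsid", "phenotype", "p_value")
  if (!all(need %in% names(df))) {
    stop("reference catalog must provide columns: ",
         paste(need, collapse = ", "))
  }
  df$pmid <- as.character(df$pmid)
  stopifnot(all(grepl(RE_RSID, df$rsid, perl = TRUE)),
            all(df$p_value > 0 & df$p_value <= 1))
  tibble::as_tibble(df[, need])
}

#' Read a phenotype mapping table
#'
#' @param path 3-column TSV: `extracted`, `reference`, `level` with level
#'   in `exact`/`approximate`.
#' @return A mapping tibble (phenotypes normalized for lookup).
#' @export
read_phenotype_mapping <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(c("extracted", "reference", "level") %in% names(df)),
            all(df$level %in% c("exact", "approximate")))
  tibble::as_tibble(df)
}

# level of equivalence between one extracted phenotype string and one
# reference phenotype string: "exact", "approximate" or "none"
phenotype_match_level <- function(extracted, reference, mapping = NULL) {
  e <- norm_phenotype(extracted)
  r <- norm_phenotype(reference)
  if (!is.na(e) && !is.na(r) && e == r) return("exact")
  if (!is.null(mapping) && nrow(mapping)) {
    hit <- norm_phenotype(mapping$extracted) == e &
      norm_phenotype(mapping$reference) == r
    hit[is.na(hit)] <- FALSE
    if (any(hit)) {
      lv <- mapping$level[hit]
      return(if ("exact" %in% lv) "exact" else "approximate")
    }
  }
  "none"
}

# all phenotype strings an extracted record offers for matching
extracted_phenotypes <- function(rec) {
  grab <- function(nm) if (nm %in% names(rec)) rec[[nm]] else character()
  out <- c(grab("resolved_phenotype"), grab("precise_phenotype"),
           grab("phenotype"))
  simple <- grab("simple_phenotypes")
  if (length(simple) && !is.na(simple)) {
    out <- c(out, strsplit(simple, "|", fixed = TRUE)[[1]])
  }
  out <- out[!is.na(out)]
  unique(out[nzchar(out)])
}

# best match level between one extracted record and a reference phenotype
record_match_level <- function(rec, ref_phenotype, mapping) {
  levels <- vapply(extracted_phenotypes(rec), phenotype_match_level,
                   "", reference = ref_phenotype, mapping = mapping)
  if ("exact" %in% levels) "exact"
  else if ("approximate" %in% levels) "approximate"
  else "none"
}

#' Match extracted associations against a reference catalog
#'
#' A reference record is recovered when some extracted record shares its
#' pmid and rsid and one of the extracted record's phenotypes (resolved,
#' precise, or any simple phenotype) matches the reference phenotype at
#' least at the requested level; `"approximate"` accepts exact matches
#' too.
#'
#' @param extracted An association tibble ([extract_corpus()] output or
#'   [read_associations()]).
#' @param reference A reference tibble ([read_reference()]).
#' @param mapping Optional phenotype mapping tibble
#'   ([read_phenotype_mapping()]).
#' @param level `"exact"` or `"approximate"`.
#' @param check_pvalue Optional relative tolerance; when non-`NULL`, a
#'   recovery additionally requires an extracted p-value within that
#'   relative tolerance of the reference p-value.
#' @return A list with `recall`, `n_recovered`, `n_reference`, and
#'   `recovered` (logical vector over reference rows).
#' @export
match_associations <- function(extracted, reference, mapping = NULL,
                               level = c("approximate", "exact"),
                               check_pvalue = NULL) {
  level <- match.arg(level)
  ok_level <- if (level == "exact") "exact" else c("exact", "approximate")
  recovered <- vapply(seq_len(nrow(reference)), function(i) {
    ref <- reference[i, ]
    cand <- extracted[extracted$pmid == ref$pmid &
                        tolower(extracted$rsid) == tolower(ref$rsid), ]
    if (!nrow(cand)) return(FALSE)
    if (!is.null(check_pvalue)) {
      keep <- abs(cand$p_value - ref$p_value) <=
        check_pvalue * abs(ref$p_value)
      cand <- cand[keep, ]
      if (!nrow(cand)) return(FALSE)
    }
    any(vapply(seq_len(nrow(cand)), function(j) {
      record_match_level(cand[j, ], ref$phenotype, mapping) %in% ok_level
    }, TRUE))
  }, TRUE)
  list(recall = if (nrow(reference)) mean(recovered) else NA_real_,
       n_recovered = sum(recovered), n_reference = nrow(reference),
       recovered = recovered)
}

#' Estimate phenotype precision on catalog-confirmed records
#'
#' Restricts to extracted records whose (pmid, rsid) pair occurs in the
#' reference (the variant is confirmed, though not necessarily with the
#' same phenotype), then returns the fraction of those records whose
#' phenotype matches some reference phenotype for that (pmid, rsid) at the
#' requested level.
#'
#' @inheritParams match_associations
#' @return A list with `precision`, `n_confirmed`, `n_correct`.
#' @export
estimate_phenotype_precision <- function(extracted, reference,
                                         mapping = NULL,
                                         level = c("approximate", "exact")) {
  level <- match.arg(level)
  ok_level <- if (level == "exact") "exact" else c("exact", "approximate")
  key <- paste(reference$pmid, tolower(reference$rsid))
  conf <- extracted[paste(extracted$pmid, tolower(extracted$rsid)) %in% key, ]
  if (!nrow(conf)) {
    stop("no extracted records are confirmed by the reference: ",
         "phenotype precision is undefined")
  }
  correct <- vapply(seq_len(nrow(conf)), function(j) {
    rec <- conf[j, ]
    refs <- reference[reference$pmid == rec$pmid &
                        tolower(reference$rsid) == tolower(rec$rsid), ]
    any(vapply(refs$phenotype, function(rp) {
      record_match_level(rec, rp, mapping) %in% ok_level
    }, TRUE))
  }, TRUE)
  list(precision = mean(correct), n_confirmed = nrow(conf),
       n_correct = sum(correct))
}

#' Error breakdown of a reference catalog against an extraction
#'
#' Partitions the reference records into four mutually exclusive classes:
#' recovered with an exact phenotype, recovered only approximately, rsid
#' found but phenotype wrong, and variant missed entirely. The four counts
#' always sum to the reference size.
#'
#' @inheritParams match_associations
#' @return A named integer vector with components `recovered_exact`,
#'   `recovered_approx`, `wrong_phenotype`, `missed_variant`.
#' @export
error_breakdown <- function(extracted, reference, mapping = NULL) {
  classes <- vapply(seq_len(nrow(reference)), function(i) {
    ref <- reference[i, ]
    cand <- extracted[extracted$pmid == ref$pmid &
                        tolower(extracted$rsid) == tolower(ref$rsid), ]
    if (!nrow(cand)) return("missed_variant")
    levels <- vapply(seq_len(nrow(cand)), function(j) {
      record_match_level(cand[j, ], ref$phenotype, mapping)
    }, "")
    if ("exact" %in% levels) "recovered_exact"
    else if ("approximate" %in% levels) "recovered_approx"
    else "wrong_phenotype"
  }, "")
  counts <- c(recovered_exact = 0L, recovered_approx = 0L,
              wrong_phenotype = 0L, missed_variant = 0L)
  tab <- table(factor(classes, levels = names(counts)))
  counts[names(tab)] <- as.integer(tab)
  counts
}
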