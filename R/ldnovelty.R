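# Linkage-disequilibrium novelty filter.
#
# LD between two variants is measured as the squared Pearson correlation of
# their allele-dosage vectors (0/1/2 per sample) over a shared genotype
# panel; no phasing is needed. Novelty filtering is within-paper: an
# extracted variant correlated above the threshold with a known curated
# variant of the same paper is dropped, and among the survivors, later
# variants in LD with an earlier retained survivor are dropped too.

#' Squared-correlation LD between two dosage vectors
#'
#' @param dosages_a,dosages_b Equal-length numeric vectors of allele
#'   dosages (0, 1 or 2), each with nonzero variance.
#' @return The squared Pearson correlation, clamped to `[0, 1]`. Symmetric
#'   in its arguments and invariant under allele flip (`2 - dosage`).
#' @examples
#' compute_r2(c(0, 0, 1, 1), c(1, 1, 0, 0))   # perfect anti-correlation
#' @export
compute_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b),
            length(dosages_a) >= 2L)
  if (var(dosages_a) == 0 || var(dosages_b) == 0) {
    stop("r2 undefined: a dosage vector has zero variance")
  }
  min(max(cor(dosages_a, dosages_b)^2, 0), 1)
}

#' Read a genotype-dosage panel
#'
#' Accepts either a plain TSV matrix (first column the variant id,
#' remaining columns per-sample dosages in \{0, 1, 2\}) or a VCF, from
#' which dosages are derived by counting alternate alleles in the `GT`
#' field (requires the vcfR package).
#'
#' @param path Panel file path (`.vcf`/`.vcf.gz` triggers VCF parsing).
#' @return A numeric matrix with one row per variant (rownames are variant
#'   ids) and one column per sample.
#' @export
read_dosage_panel <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF panels requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1]] != "0")
    })
    rownames(dos) <- vcfR::getID(v)
    return(as_dosage_panel(dos))
  }
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  as_dosage_panel(m)
}

#' @rdname read_dosage_panel
#' @param m A numeric matrix of dosages with variant-id rownames.
#' @export
as_dosage_panel <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  vals <- m[!is.na(m)]
  if (!all(vals %in% c(0, 1, 2))) {
    stop("dosage panel entries must be 0, 1 or 2")
  }
  m
}

panel_r2 <- function(panel, a, b) {
  compute_r2(panel[a, ], panel[b, ])
}

#' Filter extracted variants for novelty by LD
#'
#' Two passes per paper: (1) drop extracted rsids whose LD with any known
#' (curated) rsid of the same paper exceeds the threshold; (2) among the
#' survivors -- ordered by ascending p-value, then rsid -- greedily drop
#' variants in LD above the threshold with an earlier retained survivor.
#' Variants absent from the panel cannot be tested and are retained with a
#' flag.
#'
#' @param extracted Tibble with `pmid`, `rsid` and optionally `p_value`
#'   (used for the pass-2 ordering).
#' @param known Tibble with `pmid`, `rsid`: the curated variants.
#' @param panel A dosage matrix from [read_dosage_panel()] /
#'   [as_dosage_panel()].
#' @param threshold LD threshold in `[0, 1]`; variants with `r2 >
#'   threshold` (strict) are considered linked. Default 0.5.
#' @return A list with `retained` (subset of `extracted`) and `results`, a
#'   per-variant tibble with `pmid`, `rsid`, `best_known`, `r2`, `status`
#'   in `retained` / `ld_with_known` / `ld_with_retained` /
#'   `not_in_panel`.
#' @export
filter_novel <- function(extracted, known, panel, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1,
            all(c("pmid", "rsid") %in% names(extracted)),
            all(c("pmid", "rsid") %in% names(known)))
  if (!"p_value" %in% names(extracted)) extracted$p_value <- NA_real_
  results <- list()
  for (pm in unique(extracted$pmid)) {
    ext <- dplyr::distinct(extracted[extracted$pmid == pm, ],
                           .data$rsid, .keep_all = TRUE)
    ext <- ext[order(ext$p_value, ext$rsid, na.last = TRUE), ]
    known_rs <- unique(known$rsid[known$pmid == pm])
    known_rs <- known_rs[known_rs %in% rownames(panel)]
    kept_in_panel <- character()
    for (i in seq_len(nrow(ext))) {
      rs <- ext$rsid[i]
      if (!rs %in% rownames(panel)) {
        results[[length(results) + 1L]] <- tibble::tibble(
          pmid = pm, rsid = rs, best_known = NA_character_,
          r2 = NA_real_, status = "not_in_panel"
        )
        next
      }
      r2k <- vapply(known_rs, function(k) panel_r2(panel, rs, k), 0)
      best <- if (length(r2k)) which.max(r2k) else integer()
      if (length(best) && r2k[best] > threshold) {
        results[[length(results) + 1L]] <- tibble::tibble(
          pmid = pm, rsid = rs, best_known = known_rs[best],
          r2 = unname(r2k[best]), status = "ld_with_known"
        )
        next
      }
      r2e <- vapply(kept_in_panel, function(k) panel_r2(panel, rs, k), 0)
      beste <- if (length(r2e)) which.max(r2e) else integer()
      if (length(beste) && r2e[beste] > threshold) {
        results[[length(results) + 1L]] <- tibble::tibble(
          pmid = pm, rsid = rs, best_known = kept_in_panel[beste],
          r2 = unname(r2e[beste]), status = "ld_with_retained"
        )
        next
      }
      kept_in_panel <- c(kept_in_panel, rs)
      best_any <- c(
        if (length(best)) stats::setNames(r2k[best], known_rs[best])
      )
      results[[length(results) + 1L]] <- tibble::tibble(
        pmid = pm, rsid = rs,
        best_known = if (length(best_any)) names(best_any)
                     else NA_character_,
        r2 = if (length(best_any)) unname(best_any) else NA_real_,
        status = "retained"
      )
    }
  }
  results <- if (length(results)) dplyr::bind_rows(results) else
    tibble::tibble(pmid = character(), rsid = character(),
                   best_known = character(), r2 = numeric(),
                   status = character())
  keep <- results$status %in% c("retained", "not_in_panel")
  key <- paste(results$pmid[keep], results$rsid[keep])
  retained <- extracted[paste(extracted$pmid, extracted$rsid) %in% key, ]
  list(retained = retained, results = results)
}
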