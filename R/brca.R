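#' Filter a variant table down to driver (pathogenic) calls
#'
#' Keeps exactly the classifications `pathogenic` and `likely_pathogenic`;
#' benign, likely benign, passenger and variants of unknown significance
#' are dropped. Classification itself (database lookup, in-silico driver
#' prediction) happens upstream; this consumes the annotated labels.
#' Idempotent.
#'
#' @param variants Variant tibble (`sample`, `gene`, `hgvs`,
#'   `classification`, ...).
#' @return The retained rows, same columns.
#' @export
filter_drivers <- function(variants) {
  bad <- setdiff(unique(variants$classification), CLASSIFICATION_LEVELS)
  if (length(bad) > 0) {
    stop("unknown classification token(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  variants[variants$classification %in% c("pathogenic", "likely_pathogenic"), ,
    drop = FALSE
  ]
}

# gene symbol upper-cased + HGVS stripped of whitespace; no liftover
variant_key <- function(gene, hgvs) {
  paste0(toupper(gene), ":", gsub("[[:space:]]", "", hgvs))
}

#' Per-sample BRCA mutation status from retained driver variants
#'
#' A sample is `mutated` when any retained (pathogenic or likely
#' pathogenic) variant falls in BRCA1 or BRCA2, otherwise `wild_type`.
#'
#' @param samples Character vector of sample ids to report (samples with
#'   no retained BRCA variant are `wild_type`).
#' @param retained A filtered variant tibble from [filter_drivers()].
#' @return A tibble `sample`, `status`, with the retained BRCA variant
#'   keys as a list-column `variants`.
#' @export
brca_status <- function(samples, retained) {
  brca <- retained[toupper(retained$gene) %in% c("BRCA1", "BRCA2"), , drop = FALSE]
  keys <- split(
    variant_key(brca$gene, brca$hgvs),
    factor(brca$sample, levels = samples)
  )
  tibble::tibble(
    sample = samples,
    status = unname(ifelse(lengths(keys) > 0, "mutated", "wild_type")),
    variants = unname(lapply(keys, unique))
  )
}

#' Mutation-level concordance between two assays
#'
#' For every sample covered by both assays (complete cases), the two
#' retained variant-key sets are compared: a pair agrees only when the
#' sets are identical (both empty counts as agreement). Pairs where both
#' assays call the sample mutated but with different variants are counted
#' as disagreement in the headline rate and additionally tallied
#' separately (`n_different_mutation`), so the alternative convention can
#' be read off. The summary also reports Cohen's kappa on the binary
#' mutated/wild-type labels.
#'
#' @param calls_a,calls_b Tibbles from [brca_status()].
#' @return A list with `per_sample` (tibble: `sample`, `status_a`,
#'   `status_b`, `agree`, `kind`) and `summary` (tibble: `n`,
#'   `agreement_rate`, `n_different_mutation`, `kappa`).
#' @export
mutation_concordance <- function(calls_a, calls_b) {
  m <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(calls_a),
      "sample",
      status_a = "status", var_a = "variants"
    ),
    dplyr::select(tibble::as_tibble(calls_b),
      "sample",
      status_b = "status", var_b = "variants"
    ),
    by = "sample"
  )
  if (nrow(m) == 0) stop("no shared samples between the two call sets", call. = FALSE)
  same_set <- purrr::map2_lgl(m$var_a, m$var_b, setequal)
  kind <- dplyr::case_when(
    same_set ~ "agree",
    m$status_a == "mutated" & m$status_b == "mutated" ~ "different_mutation",
    TRUE ~ "different_status"
  )
  per_sample <- tibble::tibble(
    sample = m$sample, status_a = m$status_a, status_b = m$status_b,
    agree = same_set, kind = kind
  )
  t <- contingency_table(
    a = sum(m$status_a == "mutated" & m$status_b == "mutated"),
    b = sum(m$status_a == "mutated" & m$status_b == "wild_type"),
    c = sum(m$status_a == "wild_type" & m$status_b == "mutated"),
    d = sum(m$status_a == "wild_type" & m$status_b == "wild_type")
  )
  list(
    per_sample = per_sample,
    summary = tibble::tibble(
      n = nrow(m),
      agreement_rate = mean(same_set),
      n_different_mutation = sum(kind == "different_mutation"),
      # degenerate margins (e.g. every sample mutated in both) leave kappa
      # undefined; report NA rather than fail the whole summary
      kappa = tryCatch(cohens_kappa(t)$kappa, error = function(e) NA_real_)
    )
  )
}
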