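#' Anchor lexicon
#'
#' A facet-keyed collection of anchor phrases plus the facet -> domain map.
#' The anchor sets define the target score space: respondent terms are scored
#' by their mean cosine similarity to each facet's anchors.
#'
#' @param anchors named list, facet name -> non-empty character vector of
#'   anchor phrases.
#' @param domain_map named character vector, facet name -> domain name,
#'   covering every facet in `anchors`.
#' @return An `anchor_lexicon` with ordered `facets`, `anchors`, `domain_map`.
#' @export
anchor_lexicon <- function(anchors, domain_map) {
  stopifnot(is.list(anchors), length(anchors) >= 1)
  facets <- names(anchors)
  if (is.null(facets) || anyDuplicated(facets))
    stop("anchor sets must be uniquely named by facet")
  if (any(vapply(anchors, length, 1L) < 1))
    stop("every facet needs at least one anchor phrase")
  missing <- setdiff(facets, names(domain_map))
  if (length(missing))
    stop("domain_map does not cover facet(s): ", paste(missing, collapse = ", "))
  structure(list(facets = facets,
                 anchors = anchors[facets],
                 domain_map = domain_map[facets]),
            class = "anchor_lexicon")
}

normalize_term <- function(x) {
  x <- tolower(enc2utf8(as.character(x)))
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Quality-control sanitization of term records
#'
#' Normalizes raw terms (lowercase, unicode NFC-style encoding, trimmed and
#' collapsed whitespace), flags stop-list junk tokens as noise, and flags
#' within-person repeats of the same normalized term beyond the first as
#' duplicates. Input order is preserved; every record gets exactly one
#' `qc_status`.
#'
#' @param records data frame with columns `pid`, `raw_term`, optionally
#'   `category`.
#' @param stoplist character vector of junk tokens (compared after
#'   normalization).
#' @return list with `records` (input plus `norm_term`, `qc_status`) and `qc`,
#'   a `qc_report` with tallies, the retention rate, and per-person retained
#'   term counts (mean/sd).
#' @export
sanitize_terms <- function(records, stoplist = default_stoplist()) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("pid", "raw_term") %in% names(records)))
  bad <- which(is.na(records$pid) | !nzchar(as.character(records$pid)))
  if (length(bad))
    stop("record(s) with empty pid at index: ", paste(head(bad, 5), collapse = ", "))
  if (!"category" %in% names(records)) records$category <- "personal"

  norm <- normalize_term(records$raw_term)
  status <- rep("retained", nrow(records))
  status[norm %in% normalize_term(stoplist)] <- "noise"
  for (pid in unique(records$pid)) {
    idx <- which(records$pid == pid & status != "noise")
    dup <- idx[duplicated(norm[idx])]
    status[dup] <- "duplicate"
  }
  records$norm_term <- norm
  records$qc_status <- status

  kept <- records[status == "retained", ]
  per_person <- table(factor(kept$pid, levels = unique(records$pid)))
  qc <- structure(list(
    total_terms = nrow(records),
    retained = sum(status == "retained"),
    duplicates_removed = sum(status == "duplicate"),
    noise_removed = sum(status == "noise"),
    retention_rate = mean(status == "retained"),
    per_person_mean = mean(per_person),
    per_person_sd = if (length(per_person) > 1) sd(per_person) else 0
  ), class = "qc_report")
  list(records = records, qc = qc)
}

# Mean-cosine similarity of every retained term against every facet's anchor
# set: rows = terms, columns = facets. The workhorse behind scoring.
similarity_matrix <- function(terms, lexicon, emb) {
  term_mat <- unit_rows(embed_text(emb, terms))
  facet_cols <- lapply(lexicon$facets, function(f) {
    anchor_mat <- unit_rows(embed_text(emb, lexicon$anchors[[f]]))
    rowMeans(term_mat %*% t(anchor_mat))
  })
  out <- do.call(cbind, facet_cols)
  dimnames(out) <- list(terms, lexicon$facets)
  out
}

#' Term-facet similarity profile of a single term
#'
#' The mean cosine similarity between the term's embedding and each anchor in
#' the facet's anchor set, for every facet. All values lie in \[-1, 1\].
#'
#' @param term character scalar (already normalized/retained).
#' @param lexicon an [anchor_lexicon()].
#' @param emb an `embedding_provider`.
#' @return named numeric vector, one similarity per facet.
#' @export
term_facet_similarity <- function(term, lexicon, emb) {
  stopifnot(inherits(lexicon, "anchor_lexicon"), length(term) == 1)
  S <- similarity_matrix(term, lexicon, emb)
  setNames(S[1, ], lexicon$facets)
}

#' Person-by-facet composites from sanitized term records
#'
#' For each person i and facet f, the raw composite `x[i, f]` is the mean
#' term-facet similarity over the person's retained terms; `Z` standardizes
#' each facet column across persons (sample sd, denominator n-1). Persons with
#' no retained terms are excluded with a warning and listed in `excluded`;
#' zero-variance facet columns are kept, zeroed in `Z`, and flagged.
#'
#' @param records sanitized records (output of [sanitize_terms()]), or a raw
#'   data frame which will be sanitized with the default stop list.
#' @param lexicon an [anchor_lexicon()].
#' @param emb an `embedding_provider`.
#' @return A `composite_matrix`: `pids`, `facets`, `X`, `Z`, `col_means`,
#'   `col_sds`, `terms_used`, `excluded`, `zero_variance_facets`.
#' @export
build_composites <- function(records, lexicon, emb) {
  if (is.data.frame(records)) records <- sanitize_terms(records)$records
  else if (is.list(records) && !is.null(records$records)) records <- records$records
  stopifnot(all(c("pid", "norm_term", "qc_status") %in% names(records)))
  kept <- records[records$qc_status == "retained", , drop = FALSE]

  all_pids <- unique(records$pid)
  counts <- table(factor(kept$pid, levels = all_pids))
  excluded <- names(counts)[counts == 0]
  if (length(excluded))
    warning("excluding participant(s) with no retained terms: ",
            paste(excluded, collapse = ", "))
  pids <- setdiff(all_pids, excluded)

  uniq_terms <- unique(kept$norm_term)
  S <- similarity_matrix(uniq_terms, lexicon, emb)
  idx <- match(kept$norm_term, uniq_terms)
  X <- rowsum(S[idx, , drop = FALSE], group = factor(kept$pid, levels = pids))
  X <- X / as.numeric(counts[pids])

  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[is.na(sdv)] <- 0  # single-person input: no cross-person variance
  flagged <- lexicon$facets[sdv == 0]
  Z <- sweep(X, 2, mu, "-")
  Z <- sweep(Z, 2, ifelse(sdv > 0, sdv, 1), "/")
  Z[, sdv == 0] <- 0

  structure(list(pids = pids, facets = lexicon$facets, X = X, Z = Z,
                 col_means = mu, col_sds = sdv,
                 terms_used = setNames(as.integer(counts[pids]), pids),
                 excluded = excluded, zero_variance_facets = flagged,
                 domain_map = lexicon$domain_map),
            class = "composite_matrix")
}

#' Domain composites as unweighted means of facet composites
#'
#' @param cm a `composite_matrix`.
#' @param lexicon an [anchor_lexicon()] whose `domain_map` covers `cm$facets`.
#' @param use `"Z"` (default) or `"X"`: which composites to average.
#' @return person x domain numeric matrix.
#' @export
domain_composites <- function(cm, lexicon = NULL, use = c("Z", "X")) {
  use <- match.arg(use)
  dmap <- if (is.null(lexicon)) cm$domain_map else lexicon$domain_map
  missing <- setdiff(cm$facets, names(dmap))
  if (length(missing))
    stop("facet(s) missing from domain_map: ", paste(missing, collapse = ", "))
  M <- cm[[use]]
  domains <- unique(unname(dmap[cm$facets]))
  out <- sapply(domains, function(d) {
    rowMeans(M[, cm$facets[dmap[cm$facets] == d], drop = FALSE])
  })
  matrix(out, nrow(M), length(domains),
         dimnames = list(cm$pids, domains))
}

#' Per-person semantic coherence
#'
#' Mean pairwise cosine similarity among a person's retained term embeddings
#' (strict upper triangle). Persons with fewer than two retained terms get NA.
#'
#' @param records sanitized term records (with `qc_status`).
#' @param emb an `embedding_provider`.
#' @return named numeric vector, one coherence per pid.
#' @export
semantic_coherence <- function(records, emb) {
  if (is.list(records) && !is.null(records$records)) records <- records$records
  kept <- records[records$qc_status == "retained", , drop = FALSE]
  pids <- unique(records$pid)
  out <- setNames(rep(NA_real_, length(pids)), pids)
  for (pid in pids) {
    terms <- kept$norm_term[kept$pid == pid]
    if (length(terms) < 2) next
    V <- unit_rows(embed_text(emb, terms))
    C <- V %*% t(V)
    out[pid] <- mean(C[upper.tri(C)])
  }
  out
}
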