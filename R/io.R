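#' Read term records
#'
#' Reads participant term records from JSONL (one `{"pid","term","category"}`
#' object per line) or long CSV (columns `pid`, `term`, optional `category`).
#' Missing categories default to `"personal"`. Malformed rows are counted and
#' reported; more than `tolerance` of them is an error naming the first bad
#' line.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension by default.
#' @param tolerance maximum number of malformed rows to drop (default 0).
#' @return data frame with columns `pid`, `raw_term`, `category`.
#' @export
read_term_records <- function(path, format = c("auto", "jsonl", "csv"),
                              tolerance = 0) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.jsonl?$", path)) "jsonl" else "csv"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    parsed <- lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    })
    bad <- which(vapply(parsed, function(x) {
      is.null(x) || is.null(x$pid) || is.null(x$term)
    }, logical(1)))
    if (length(bad) > tolerance)
      stop("malformed JSONL row(s), first at line ", bad[1])
    parsed <- parsed[setdiff(seq_along(parsed), bad)]
    out <- data.frame(
      pid = vapply(parsed, function(x) as.character(x$pid), ""),
      raw_term = vapply(parsed, function(x) as.character(x$term), ""),
      category = vapply(parsed, function(x) {
        if (is.null(x$category)) "personal" else as.character(x$category)
      }, ""),
      stringsAsFactors = FALSE)
  } else {
    out <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!"pid" %in% names(out)) stop("missing required column: pid")
    if (!"term" %in% names(out)) stop("missing required column: term")
    bad <- which(!nzchar(out$pid) | is.na(out$pid))
    if (length(bad) > tolerance)
      stop("malformed CSV row(s), first at line ", bad[1] + 1)
    out <- out[setdiff(seq_len(nrow(out)), bad), , drop = FALSE]
    if (!"category" %in% names(out)) out$category <- "personal"
    out <- data.frame(pid = out$pid, raw_term = out$term,
                      category = out$category, stringsAsFactors = FALSE)
  }
  out
}

#' Write term records
#'
#' @param records data frame with `pid`, `raw_term`, `category`.
#' @param path output path.
#' @param format `"jsonl"` or `"csv"`.
#' @export
write_term_records <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      jsonlite::toJSON(list(pid = records$pid[i], term = records$raw_term[i],
                            category = records$category[i]),
                       auto_unbox = TRUE)
    }, "")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    write.csv(data.frame(pid = records$pid, term = records$raw_term,
                         category = records$category),
              path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a wide person-by-facet score table
#'
#' First column is the person id; remaining columns are facets. Non-numeric
#' cells become NA with a warning; duplicate pids are an error.
#'
#' @param path CSV path.
#' @return numeric matrix with pid rownames.
#' @export
read_scores_wide <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) < 2) stop("wide score table needs a pid column plus facets")
  pids <- as.character(raw[[1]])
  if (anyDuplicated(pids)) stop("duplicate pid(s) in ", path)
  vals <- raw[, -1, drop = FALSE]
  n_bad <- 0
  M <- vapply(vals, function(col) {
    x <- suppressWarnings(as.numeric(col))
    n_bad <<- n_bad + sum(is.na(x) & !is.na(col) & nzchar(as.character(col)))
    x
  }, numeric(nrow(raw)))
  M <- matrix(M, nrow(raw), dimnames = list(pids, names(vals)))
  if (n_bad > 0) warning(n_bad, " non-numeric cell(s) set to NA")
  M
}

#' Write a wide person-by-facet score table
#'
#' @param M numeric matrix with pid rownames.
#' @param path CSV path.
#' @export
write_scores_wide <- function(M, path) {
  df <- data.frame(pid = rownames(M), M, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write composites in long format
#'
#' @param cm a `composite_matrix`.
#' @param path CSV path (columns pid, facet, value — standardized scores).
#' @export
write_composites_long <- function(cm, path) {
  df <- data.frame(pid = rep(cm$pids, times = length(cm$facets)),
                   facet = rep(cm$facets, each = length(cm$pids)),
                   value = as.vector(cm$Z))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write cohort inputs to a directory
#'
#' Serializes a synthetic cohort the way real study inputs arrive: term
#' records as JSONL and long CSV, questionnaire scores as wide CSV, the
#' anchor lexicon and ground truth as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    terms_jsonl = file.path(dir, "term_records.jsonl"),
    terms_csv = file.path(dir, "term_records.csv"),
    b5 = file.path(dir, "b5_scores.csv"),
    lexicon = file.path(dir, "anchor_lexicon.json"),
    truth = file.path(dir, "ground_truth.json"))
  write_term_records(cohort$term_records, paths$terms_jsonl, "jsonl")
  write_term_records(cohort$term_records, paths$terms_csv, "csv")
  write_scores_wide(cohort$b5_scores, paths$b5)
  jsonlite::write_json(list(anchors = cohort$anchor_lexicon$anchors,
                            domain_map = as.list(cohort$anchor_lexicon$domain_map)),
                       paths$lexicon, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(as.list(cohort$ground_truth_partition), paths$truth,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read an anchor lexicon from JSON
#'
#' @param path JSON with `anchors` (facet -> phrase list) and `domain_map`.
#' @return an [anchor_lexicon()].
#' @export
read_anchor_lexicon <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  anchor_lexicon(anchors = as.list(obj$anchors),
                 domain_map = unlist(obj$domain_map))
}

#' Run the full analysis pipeline
#'
#' Strings the stages together on in-memory inputs: QC sanitization, anchor
#' scoring into standardized composites, per-domain reliability, the
#' partial-correlation network with stability diagnostics and communities
#' (for the scored composites and for the comparison scores), person-level
#' convergence, and configuration alignment between the two anchor lexicons.
#' Stage failures mark the report partial and skip downstream stages;
#' upstream results are preserved.
#'
#' @param term_records data frame (pid, raw_term, category).
#' @param lexicon an [anchor_lexicon()] defining the score space.
#' @param emb an `embedding_provider`.
#' @param b5_scores person x facet matrix of comparison questionnaire scores.
#' @param b5_lexicon optional comparison-instrument lexicon; when supplied the
#'   comparison network is built from its descriptors scored through the same
#'   semantic path, and the alignment block compares the two lexicons.
#' @param matching DM domain -> comparison domain map for convergence
#'   (default: shared domain names).
#' @param seed master seed for every stochastic stage.
#' @param n_boot bootstrap replicates for reliability/stability stages.
#' @param n_perm Mantel permutations.
#' @param stoplist QC stop list.
#' @param gamma EBIC hyperparameter.
#' @param n_lambda path points for network estimation.
#' @param b5_network_source `"semantic"` (default; comparison network from
#'   descriptors scored through the same semantic path, needs `b5_lexicon`)
#'   or `"composites"` (questionnaire facet scores).
#' @return A `run_report` list with elements `qc`, `composites`,
#'   `reliability`, `network`, `convergence`, `alignment`, `provenance`,
#'   and `status`/`failed_stage` when partial.
#' @export
run_full_analysis <- function(term_records, lexicon, emb, b5_scores = NULL,
                              b5_lexicon = NULL, matching = NULL, seed = 1L,
                              n_boot = 200, n_perm = 1000,
                              stoplist = default_stoplist(), gamma = 0.5,
                              n_lambda = 40,
                              b5_network_source = c("semantic", "composites")) {
  b5_network_source <- match.arg(b5_network_source)
  report <- list(status = "complete", failed_stage = NULL)
  run_stage <- function(name, expr) {
    if (!is.null(report$failed_stage)) return(NULL)
    tryCatch(expr, error = function(e) {
      report$status <<- "partial"
      report$failed_stage <<- paste0(name, ": ", conditionMessage(e))
      NULL
    })
  }

  san <- run_stage("qc", sanitize_terms(term_records, stoplist))
  report$qc <- san$qc

  cm <- run_stage("scoring", build_composites(san$records, lexicon, emb))
  report$composites <- cm

  report$reliability <- run_stage("reliability", {
    domains <- unique(unname(lexicon$domain_map))
    out <- lapply(domains, function(d) {
      cols <- lexicon$facets[lexicon$domain_map == d]
      k <- length(cols)
      reliability_report(cm$Z[, cols, drop = FALSE], domain = d,
                         n_groups = if (k >= 6) 2 else NA,
                         n_boot = n_boot, seed = derive_seed(seed, 10L))
    })
    setNames(out, domains)
  })

  report$network <- run_stage("network", {
    one_side <- function(data, tag) {
      net <- estimate_network(data, gamma = gamma, n_lambda = n_lambda)
      part <- louvain_communities(net, seed = derive_seed(seed, 20L))
      eb <- edge_bootstrap(data, n_boot = n_boot,
                           seed = derive_seed(seed, 21L), gamma = gamma,
                           n_lambda = n_lambda)
      cs <- case_drop_cs(data, "strength", n_boot = n_boot,
                         seed = derive_seed(seed, 22L), gamma = gamma,
                         n_lambda = n_lambda)
      rec <- structure_recovery_frequency(data, reference = part,
                                          n_boot = max(50, n_boot %/% 4),
                                          seed = derive_seed(seed, 23L),
                                          gamma = gamma, n_lambda = n_lambda)
      list(model = net, communities = part, globals = global_metrics(net),
           cs_strength = as.numeric(cs),
           edge_mean_retention = eb$edge_mean_retention,
           edge_median_weight_corr = eb$edge_median_weight_corr,
           recovery_frequency = rec, tag = tag)
    }
    out <- list(dm = one_side(cm$Z, "dm"))
    if (b5_network_source == "semantic" && !is.null(b5_lexicon)) {
      # comparison network from descriptors scored through the identical
      # semantic path: the retained terms projected onto the other
      # instrument's anchor space
      cm_b5 <- build_composites(san$records, b5_lexicon, emb)
      out$b5 <- one_side(cm_b5$Z, "b5")
    } else if (!is.null(b5_scores)) {
      out$b5 <- one_side(scale(b5_scores), "b5")
    }
    out
  })

  if (!is.null(b5_scores)) {
    report$convergence <- run_stage("convergence", {
      dm_dom <- domain_composites(cm, lexicon)
      b5_lex <- if (is.null(b5_lexicon)) lexicon else b5_lexicon
      b5z <- scale(b5_scores)
      b5_cm <- structure(list(pids = rownames(b5_scores),
                              facets = colnames(b5_scores),
                              Z = b5z, X = b5_scores,
                              domain_map = b5_lex$domain_map),
                         class = "composite_matrix")
      b5_dom <- domain_composites(b5_cm, b5_lex)
      convergence_matrix(dm_dom, b5_dom, matching = matching,
                         dm_facets = cm$Z, b5_facets = b5z)
    })
  }

  report$alignment <- run_stage("alignment", {
    b5_lex <- if (is.null(b5_lexicon)) lexicon else b5_lexicon
    fc <- facet_configurations(lexicon, b5_lex, emb)
    alignment_report(fc$X, fc$Y, n_perm = n_perm,
                     seed = derive_seed(seed, 30L))
  })

  report$provenance <- list(seed = seed, n_boot = n_boot, n_perm = n_perm,
                            gamma = gamma, n_lambda = n_lambda,
                            embedding = emb$name,
                            package_version = as.character(
                              utils::packageVersion("semanchor")))
  class(report) <- "run_report"
  report
}

#' Serialize a run report to JSON
#'
#' Writes the numeric summary of a [run_full_analysis()] report. Content is
#' deterministic for a fixed config and seed (no timestamps).
#'
#' @param report a `run_report`.
#' @param path output JSON path.
#' @export
write_run_report <- function(report, path) {
  summarize_rel <- function(r) {
    list(domain = r$domain, k = r$k, omega_total = r$omega_total,
         omega_h = if (is.na(r$omega_h)) NULL else r$omega_h,
         ci = c(r$ci_low, r$ci_high),
         mean_item_total = mean(r$item_total, na.rm = TRUE),
         max_abs_loo_delta_omega = max(abs(r$loo_delta_omega), na.rm = TRUE))
  }
  summarize_net <- function(s) {
    list(lambda = s$model$lambda_selected, q = s$communities$Q,
         n_communities = length(unique(s$communities$membership)),
         global_strength = s$globals$global_strength,
         density = s$globals$density, cs_strength = s$cs_strength,
         edge_mean_retention = s$edge_mean_retention,
         edge_median_weight_corr = s$edge_median_weight_corr,
         recovery_frequency = s$recovery_frequency)
  }
  out <- list(
    status = report$status,
    failed_stage = report$failed_stage,
    qc = unclass(report$qc),
    excluded = report$composites$excluded,
    reliability = lapply(report$reliability, summarize_rel),
    network = lapply(Filter(function(x) is.list(x) && !is.null(x$model),
                            report$network), summarize_net),
    convergence = if (!is.null(report$convergence)) list(
      matched_mean_abs_r = report$convergence$matched_mean_abs_r,
      matched_range = report$convergence$matched_range,
      max_abs_facet_r = report$convergence$facet$max_abs),
    alignment = if (!is.null(report$alignment))
      unclass(report$alignment),
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
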