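test_that("sanitizer flags duplicates and noise exactly once each", {
  rec <- data.frame(pid = c("a", "a", "a", "b", "b"),
                    raw_term = c("Calm ", "calm", "bold", "nan", "focus"))
  out <- sanitize_terms(rec)
  expect_equal(out$records$qc_status,
               c("retained", "duplicate", "retained", "noise", "retained"))
  expect_equal(out$qc$duplicates_removed, 1)
  expect_equal(out$qc$noise_removed, 1)
  expect_equal(out$qc$retention_rate, 3 / 5)
  expect_equal(out$qc$total_terms,
               out$qc$retained + out$qc$duplicates_removed + out$qc$noise_removed)
})

test_that("clean input retains everything with exact per-person stats", {
  rec <- data.frame(pid = rep(sprintf("p%02d", 1:10), each = 10),
                    raw_term = paste0("term", rep(1:10, 10), "_", rep(1:10, each = 10)))
  out <- sanitize_terms(rec)
  expect_equal(out$qc$retention_rate, 1)
  expect_equal(out$qc$per_person_mean, 10)
  expect_equal(out$qc$per_person_sd, 0)
})

test_that("empty pid is rejected with its index", {
  rec <- data.frame(pid = c("a", ""), raw_term = c("x", "y"))
  expect_error(sanitize_terms(rec), "index: 2")
})

test_that("term-facet similarity equals the loop-and-average oracle", {
  co <- tiny_cohort()
  lex <- co$anchor_lexicon
  emb <- co$embedding
  term <- attr(emb, "vocab")[[1]][2]
  s <- term_facet_similarity(term, lex, emb)
  expect_true(all(s >= -1 & s <= 1))
  et <- drop(embed_text(emb, term))
  for (f in lex$facets) {
    sims <- vapply(lex$anchors[[f]], function(a) {
      ea <- drop(embed_text(emb, a))
      sum(et * ea) / sqrt(sum(et^2) * sum(ea^2))
    }, numeric(1))
    expect_equal(unname(s[f]), mean(sims), tolerance = 1e-12)
  }
  # a single anchor identical to the term itself
  lex1 <- anchor_lexicon(anchors = list(self = term),
                         domain_map = c(self = "d"))
  expect_equal(unname(term_facet_similarity(term, lex1, emb)["self"]), 1,
               tolerance = 1e-12)
})

test_that("opposed anchor vectors cancel to zero similarity", {
  flip <- function(text) {
    v <- c(1, 0, 0, 0)
    if (text == "anti") -v else v
  }
  emb <- embedding_provider(function(text) {
    if (text == "anti") c(-1, 0, 0, 0) else if (text == "pro") c(1, 0, 0, 0)
    else c(0, 1, 0, 0)
  }, dim = 4)
  lex <- anchor_lexicon(anchors = list(f = c("pro", "anti")),
                        domain_map = c(f = "d"))
  s <- term_facet_similarity("other", lex, emb)
  expect_equal(unname(s["f"]), 0, tolerance = 1e-12)
})

test_that("hand-set similarities standardize to the expected Z columns", {
  # 3 persons x 2 facets; facet A similarities 0.2/0.4/0.6, facet B constant
  emb <- embedding_provider(function(text) {
    m <- list(t1 = c(0.2, sqrt(1 - 0.04)), t2 = c(0.4, sqrt(1 - 0.16)),
              t3 = c(0.6, 0.8), a1 = c(1, 0))
    m[[text]]
  }, dim = 2)
  lex <- anchor_lexicon(anchors = list(A = "a1"), domain_map = c(A = "d"))
  rec <- data.frame(pid = c("p1", "p2", "p3"), raw_term = c("t1", "t2", "t3"))
  cm <- build_composites(rec, lex, emb)
  expect_equal(unname(cm$X[, "A"]), c(0.2, 0.4, 0.6), tolerance = 1e-12)
  expect_equal(unname(cm$Z[, "A"]), c(-1, 0, 1), tolerance = 1e-10)
})

test_that("zero-variance facet columns are flagged and zeroed, not dropped", {
  emb <- embedding_provider(function(text) c(1, 0), dim = 2)
  lex <- anchor_lexicon(anchors = list(A = "a"), domain_map = c(A = "d"))
  rec <- data.frame(pid = c("p1", "p2"), raw_term = c("x", "y"))
  cm <- build_composites(rec, lex, emb)
  expect_equal(cm$zero_variance_facets, "A")
  expect_equal(unname(cm$Z[, "A"]), c(0, 0))
})

test_that("full scoring path matches the naive nested-loop reference", {
  co <- tiny_cohort(n_persons = 6, seed = 21)
  cm <- build_composites(co$term_records, co$anchor_lexicon, co$embedding)
  ref <- naive_composites(co$term_records, co$anchor_lexicon, co$embedding)
  expect_equal(cm$X[rownames(ref$X), ], ref$X, tolerance = 1e-10)
  expect_equal(cm$Z[rownames(ref$Z), ], ref$Z, tolerance = 1e-10)
  expect_true(all(cm$X >= -1 & cm$X <= 1))
  expect_equal(unname(colMeans(cm$Z)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(cm$Z, 2, sd)), rep(1, 6), tolerance = 1e-10)
})

test_that("scoring is invariant to record order and dedup is idempotent", {
  co <- tiny_cohort(n_persons = 6, seed = 13)
  rec <- co$term_records
  cm1 <- build_composites(rec, co$anchor_lexicon, co$embedding)
  perm <- withr::with_seed(1, sample.int(nrow(rec)))
  cm2 <- build_composites(rec[perm, ], co$anchor_lexicon, co$embedding)
  expect_equal(cm1$X[cm1$pids, ], cm2$X[cm1$pids, ], tolerance = 1e-12)
  # appending a duplicate of an existing term changes nothing
  extra <- rbind(rec, rec[1, ])
  cm3 <- build_composites(extra, co$anchor_lexicon, co$embedding)
  expect_equal(cm1$X, cm3$X[rownames(cm1$X), ], tolerance = 1e-12)
})

test_that("persons with no retained terms are excluded with a warning", {
  co <- tiny_cohort(n_persons = 4, seed = 3)
  rec <- co$term_records
  bad <- data.frame(pid = "zz", raw_term = c("nan", "n/a"), category = "personal")
  rec <- rbind(rec, bad)
  expect_warning(cm <- build_composites(rec, co$anchor_lexicon, co$embedding),
                 "zz")
  expect_equal(cm$excluded, "zz")
  expect_false("zz" %in% cm$pids)
})

test_that("domain composites equal brute-force row means of facet columns", {
  co <- tiny_cohort(n_persons = 10, seed = 17)
  cm <- build_composites(co$term_records, co$anchor_lexicon, co$embedding)
  dom <- domain_composites(cm, co$anchor_lexicon)
  dmap <- co$anchor_lexicon$domain_map
  for (d in unique(unname(dmap))) {
    ref <- rowMeans(cm$Z[, names(dmap)[dmap == d], drop = FALSE])
    expect_equal(unname(dom[, d]), unname(ref), tolerance = 1e-12)
  }
  # identical facet columns collapse to themselves
  cm2 <- cm
  for (f in names(dmap)[dmap == dmap[[1]]]) cm2$Z[, f] <- cm$Z[, 1]
  dom2 <- domain_composites(cm2)
  expect_equal(unname(dom2[, dmap[[1]]]), unname(cm$Z[, 1]), tolerance = 1e-12)
})

test_that("semantic coherence matches the pairwise-cosine oracle", {
  co <- tiny_cohort(n_persons = 5, seed = 23)
  san <- sanitize_terms(co$term_records)
  coh <- semantic_coherence(san, co$embedding)
  pid <- names(coh)[1]
  terms <- san$records$norm_term[san$records$pid == pid &
                                   san$records$qc_status == "retained"]
  V <- embed_text(co$embedding, terms)
  sims <- c()
  for (i in seq_len(length(terms) - 1)) {
    for (j in (i + 1):length(terms)) {
      sims <- c(sims, sum(V[i, ] * V[j, ]) /
                  sqrt(sum(V[i, ]^2) * sum(V[j, ]^2)))
    }
  }
  expect_equal(unname(coh[pid]), mean(sims), tolerance = 1e-12)
  # degenerate cases
  one <- data.frame(pid = "a", raw_term = "solo",
                    norm_term = "solo", qc_status = "retained")
  expect_true(is.na(semantic_coherence(one, co$embedding)["a"]))
})
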