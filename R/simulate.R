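#' Simulation configuration
#'
#' Parameters of the synthetic-cohort generator. Defaults emulate the study
#' situation the package targets: five trait domains with six facets each,
#' respondents producing ~20 short descriptor terms split between personal and
#' professional prompts, a small rate of within-person duplicate terms and
#' junk tokens, and questionnaire facet scores whose convergence with the
#' latent traits is a dial (`b5_convergence_c`).
#'
#' @param n_persons number of simulated respondents.
#' @param n_domains,facets_per_domain latent trait hierarchy (default 5 x 6).
#' @param vocab_per_facet vocabulary terms generated per facet.
#' @param anchors_per_facet anchor phrases per facet in the generated lexicon.
#' @param embed_dim embedding dimension of the geometric space.
#' @param domain_cohesion in \[0,1\]: weight of the shared domain direction in
#'   each facet centroid; 1 collapses a domain's facets onto one direction.
#' @param anchor_concentration noise scale of anchors/terms around their facet
#'   centroid; smaller is tighter.
#' @param facet_loading_a in \[0,1\]: loading of the latent domain score on
#'   each of its facet scores.
#' @param terms_per_person terms emitted per respondent.
#' @param emission_temperature softmax temperature for facet choice; lower
#'   concentrates a person's terms on their strongest facets.
#' @param dup_rate probability in \[0,1) that an emitted slot repeats one of
#'   the person's earlier terms.
#' @param noise_rate probability in \[0,1) that a slot emits a junk token.
#' @param b5_convergence_c in \[0,1\]: loading of the latent facet score on the
#'   observed questionnaire facet score.
#' @param n_raters simulated expert raters.
#' @param seed master seed; fully determines every generated artifact.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_persons = 200, n_domains = 5, facets_per_domain = 6,
                       vocab_per_facet = 8, anchors_per_facet = 4,
                       embed_dim = 64, domain_cohesion = 0.8,
                       anchor_concentration = 0.35, facet_loading_a = 0.8,
                       terms_per_person = 20, emission_temperature = 1,
                       dup_rate = 0.126, noise_rate = 0.02,
                       b5_convergence_c = 0.6, n_raters = 3, seed = 1L) {
  cfg <- list(n_persons = as.integer(n_persons), n_domains = as.integer(n_domains),
              facets_per_domain = as.integer(facets_per_domain),
              vocab_per_facet = as.integer(vocab_per_facet),
              anchors_per_facet = as.integer(anchors_per_facet),
              embed_dim = as.integer(embed_dim),
              domain_cohesion = domain_cohesion,
              anchor_concentration = anchor_concentration,
              facet_loading_a = facet_loading_a,
              terms_per_person = as.integer(terms_per_person),
              emission_temperature = emission_temperature,
              dup_rate = dup_rate, noise_rate = noise_rate,
              b5_convergence_c = b5_convergence_c,
              n_raters = as.integer(n_raters), seed = as.integer(seed))
  stopifnot(cfg$n_persons >= 1, cfg$n_domains >= 1, cfg$facets_per_domain >= 1,
            cfg$vocab_per_facet >= 1, cfg$anchors_per_facet >= 1,
            cfg$embed_dim >= 2,
            cfg$domain_cohesion >= 0, cfg$domain_cohesion <= 1,
            cfg$anchor_concentration > 0,
            cfg$facet_loading_a >= 0, cfg$facet_loading_a <= 1,
            cfg$terms_per_person >= 1, cfg$emission_temperature > 0,
            cfg$dup_rate >= 0, cfg$dup_rate < 1,
            cfg$noise_rate >= 0, cfg$noise_rate < 1,
            cfg$b5_convergence_c >= 0, cfg$b5_convergence_c <= 1,
            cfg$n_raters >= 1)
  class(cfg) <- "sim_config"
  cfg
}

domain_labels <- function(cfg) sprintf("dom%02d", seq_len(cfg$n_domains))

facet_labels <- function(cfg) {
  unlist(lapply(seq_len(cfg$n_domains), function(d) {
    sprintf("dom%02d_fac%02d", d, seq_len(cfg$facets_per_domain))
  }))
}

#' Default junk-token stop list
#'
#' Tokens treated as noise during quality control (missing-value artifacts and
#' boilerplate strings typical of scraped open-response exports).
#' @return character vector.
#' @export
default_stoplist <- function() c("nan", "n/a", "", "lorem", "click here")

#' Simulate a complete synthetic cohort
#'
#' Generates latent domain scores (standard normal), latent facet scores
#' `a * domain + sqrt(1 - a^2) * noise`, per-person term emissions (facet
#' chosen by softmax over the person's latent facet scores, then a vocabulary
#' term of that facet; slots become junk tokens with probability `noise_rate`
#' and duplicates of earlier terms with probability `dup_rate`), questionnaire
#' facet scores `c * facet + sqrt(1 - c^2) * noise` rescaled to a T-score
#' metric (mean 50, sd 10), and the anchor lexicon / embedding space the
#' scoring stage needs.
#'
#' @param cfg a [sim_config()].
#' @return A `synthetic_cohort` list: `term_records` data frame (pid, raw_term,
#'   category), `anchor_lexicon`, `embedding` provider, `b5_scores` and latent
#'   matrices, and `ground_truth_partition` (facet -> domain).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  emb <- make_embedding_space(cfg)
  facets <- facet_labels(cfg)
  domains <- domain_labels(cfg)
  n_fac <- length(facets)
  domain_of <- rep(seq_len(cfg$n_domains), each = cfg$facets_per_domain)
  vocab <- attr(emb, "vocab")
  stop_pool <- default_stoplist()
  stop_pool <- stop_pool[nzchar(stop_pool)]

  out <- with_seed(derive_seed(cfg$seed, 2L), {
    theta <- matrix(rnorm(cfg$n_persons * cfg$n_domains), cfg$n_persons,
                    dimnames = list(NULL, domains))
    a <- cfg$facet_loading_a
    eta <- sapply(seq_len(n_fac), function(f) {
      a * theta[, domain_of[f]] + sqrt(1 - a^2) * rnorm(cfg$n_persons)
    })
    eta <- matrix(eta, cfg$n_persons, n_fac, dimnames = list(NULL, facets))

    pids <- sprintf("p%04d", seq_len(cfg$n_persons))
    rec_pid <- rec_term <- rec_cat <- vector("list", cfg$n_persons)
    for (i in seq_len(cfg$n_persons)) {
      probs <- exp(eta[i, ] / cfg$emission_temperature)
      probs <- probs / sum(probs)
      emitted <- character(cfg$terms_per_person)
      for (s in seq_len(cfg$terms_per_person)) {
        u <- runif(1)
        if (u < cfg$noise_rate) {
          emitted[s] <- sample(stop_pool, 1)
        } else if (u < cfg$noise_rate + cfg$dup_rate && s > 1) {
          emitted[s] <- sample(emitted[seq_len(s - 1)], 1)
        } else {
          # fresh emission: sample a facet, then an unused term of that facet,
          # so accidental repeats cannot masquerade as injected duplicates
          p <- probs
          term <- NULL
          while (is.null(term)) {
            f <- sample.int(n_fac, 1, prob = p)
            avail <- setdiff(vocab[[f]], emitted)
            if (length(avail)) {
              term <- sample(avail, 1)
            } else {
              p[f] <- 0
              if (all(p == 0)) { # vocabulary exhausted: allow a repeat
                f <- sample.int(n_fac, 1, prob = probs)
                term <- sample(vocab[[f]], 1)
              }
            }
          }
          emitted[s] <- term
        }
      }
      rec_pid[[i]] <- rep(pids[i], cfg$terms_per_person)
      rec_term[[i]] <- emitted
      rec_cat[[i]] <- rep(c("professional", "personal"),
                          length.out = cfg$terms_per_person)
    }
    term_records <- data.frame(pid = unlist(rec_pid), raw_term = unlist(rec_term),
                               category = unlist(rec_cat),
                               stringsAsFactors = FALSE)

    cc <- cfg$b5_convergence_c
    b5 <- sapply(seq_len(n_fac), function(f) {
      z <- cc * eta[, f] + sqrt(1 - cc^2) * rnorm(cfg$n_persons)
      50 + 10 * z
    })
    b5 <- matrix(b5, cfg$n_persons, n_fac, dimnames = list(pids, facets))
    rownames(theta) <- rownames(eta) <- pids
    list(term_records = term_records, theta = theta, eta = eta, b5 = b5)
  })

  lex <- anchor_lexicon(
    anchors = attr(emb, "anchors"),
    domain_map = setNames(domains[domain_of], facets)
  )
  structure(list(term_records = out$term_records,
                 anchor_lexicon = lex,
                 embedding = emb,
                 b5_scores = out$b5,
                 latent_domains = out$theta,
                 latent_facets = out$eta,
                 ground_truth_partition = setNames(domains[domain_of], facets),
                 config = cfg),
            class = "synthetic_cohort")
}

#' Simulate ordinal expert ratings
#'
#' Draws latent target scores, adds per-rater bias and measurement error, then
#' rounds and clamps to the 1-5 ordinal scale used by content-rating
#' worksheets. The latent true scores are attached for recovery testing.
#'
#' @param n_targets,n_raters matrix dimensions (each at least 2).
#' @param true_sd sd of latent target scores (centered at scale midpoint 3).
#' @param rater_bias_sd sd of rater-specific additive bias.
#' @param error_sd sd of the residual rating error.
#' @param seed RNG seed.
#' @return integer matrix targets x raters with attribute `true_scores`.
#' @export
simulate_ratings <- function(n_targets, n_raters, true_sd = 1,
                             rater_bias_sd = 0.3, error_sd = 0.5, seed = 1L) {
  stopifnot(n_targets >= 2, n_raters >= 2)
  if (true_sd <= 0 || rater_bias_sd < 0 || error_sd < 0)
    stop("rating-model sds must be positive (true_sd) or non-negative")
  with_seed(seed, {
    true <- 3 + rnorm(n_targets, sd = true_sd)
    bias <- rnorm(n_raters, sd = rater_bias_sd)
    err <- matrix(rnorm(n_targets * n_raters, sd = error_sd), n_targets)
    raw <- outer(true, bias, "+") + err
    ratings <- matrix(pmin(5L, pmax(1L, as.integer(round(raw)))), n_targets,
                      dimnames = list(sprintf("t%03d", seq_len(n_targets)),
                                      sprintf("r%02d", seq_len(n_raters))))
    attr(ratings, "true_scores") <- true
    ratings
  })
}
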