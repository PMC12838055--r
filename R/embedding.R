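#' Embedding providers
#'
#' An embedding provider is a deterministic map from text to a fixed-length
#' unit vector. The scoring pipeline is agnostic to where the vectors come
#' from: any pretrained sentence encoder can be wrapped in the same contract.
#' The package ships a geometric provider ([make_embedding_space()]) whose
#' vectors are generated around known facet centroids, so every downstream
#' statistic can be validated against planted ground truth without model
#' downloads.
#'
#' @param embed_fun function taking a character scalar and returning a numeric
#'   vector of length `dim`.
#' @param dim embedding dimension.
#' @param name backend label stored for provenance.
#' @return An object of class `embedding_provider`.
#' @export
embedding_provider <- function(embed_fun, dim, name = "custom") {
  stopifnot(is.function(embed_fun), dim >= 2)
  structure(list(embed_fun = embed_fun, dim = as.integer(dim), name = name),
            class = "embedding_provider")
}

#' Embed a character vector
#'
#' @param provider an `embedding_provider`.
#' @param texts character vector; empty strings are an error.
#' @return numeric matrix, one unit row per input text.
#' @export
embed_text <- function(provider, texts) {
  stopifnot(inherits(provider, "embedding_provider"))
  if (any(!nzchar(texts))) stop("cannot embed an empty string")
  out <- vapply(texts, provider$embed_fun, numeric(provider$dim))
  t(out)
}

# Seeded-hash fallback: any string maps to a reproducible unit vector.
hash_vector <- function(text, dim, salt = 0L) {
  with_seed(derive_seed(string_hash(text), salt), unit(rnorm(dim)))
}

#' Geometric embedding space with planted facet structure
#'
#' Builds a deterministic embedding space in which each facet has a centroid
#' that mixes a shared domain direction (weight `domain_cohesion`) with a
#' facet-specific direction, and each vocabulary term / anchor phrase is a
#' noisy copy of its facet centroid (noise scale `anchor_concentration`).
#' Strings outside the generated vocabulary fall back to a seeded-hash unit
#' vector, so arbitrary text remains embeddable.
#'
#' @param cfg a [sim_config()].
#' @return An `embedding_provider` with attributes `vocab` (facet-keyed term
#'   lists), `anchors` (facet-keyed anchor phrase lists), `centroids`
#'   (facet-by-dim matrix) and `facet_names`.
#' @export
make_embedding_space <- function(cfg) {
  stopifnot(cfg$embed_dim >= 2)
  d <- cfg$embed_dim
  n_fac <- cfg$n_domains * cfg$facets_per_domain
  facet_names <- facet_labels(cfg)
  domain_of <- rep(seq_len(cfg$n_domains), each = cfg$facets_per_domain)

  geom <- with_seed(derive_seed(cfg$seed, 1L), {
    dom_dirs <- t(vapply(seq_len(cfg$n_domains),
                         function(i) unit(rnorm(d)), numeric(d)))
    fac_dirs <- t(vapply(seq_len(n_fac),
                         function(i) unit(rnorm(d)), numeric(d)))
    # loading parametrization: within-domain centroid cosine ~ w^2
    w <- cfg$domain_cohesion
    centroids <- t(vapply(seq_len(n_fac), function(f) {
      unit(w * dom_dirs[domain_of[f], ] + sqrt(1 - w^2) * fac_dirs[f, ])
    }, numeric(d)))
    # noise scaled by 1/sqrt(d) so anchor_concentration is the expected
    # displacement norm regardless of embedding dimension
    jitter_point <- function(centroid) {
      unit(centroid + cfg$anchor_concentration * rnorm(d) / sqrt(d))
    }
    vocab <- lapply(seq_len(n_fac), function(f) {
      terms <- sprintf("%s term%02d", facet_names[f], seq_len(cfg$vocab_per_facet))
      vecs <- t(vapply(terms, function(.) jitter_point(centroids[f, ]), numeric(d)))
      rownames(vecs) <- terms
      vecs
    })
    anchors <- lapply(seq_len(n_fac), function(f) {
      phrases <- sprintf("%s anchor%02d", facet_names[f], seq_len(cfg$anchors_per_facet))
      vecs <- t(vapply(phrases, function(.) jitter_point(centroids[f, ]), numeric(d)))
      rownames(vecs) <- phrases
      vecs
    })
    list(centroids = centroids, vocab = vocab, anchors = anchors)
  })

  lookup <- do.call(rbind, c(geom$vocab, geom$anchors))
  lookup_env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(lookup))) assign(rownames(lookup)[i], lookup[i, ], envir = lookup_env)

  embed_fun <- function(text) {
    if (!nzchar(text)) stop("cannot embed an empty string")
    hit <- get0(text, envir = lookup_env, inherits = FALSE)
    if (!is.null(hit)) hit else hash_vector(text, d, salt = cfg$seed %% 1000L)
  }
  prov <- embedding_provider(embed_fun, d, name = "geometric")
  rownames(geom$centroids) <- facet_names
  attr(prov, "centroids") <- geom$centroids
  attr(prov, "vocab") <- setNames(lapply(geom$vocab, rownames), facet_names)
  attr(prov, "anchors") <- setNames(lapply(geom$anchors, rownames), facet_names)
  attr(prov, "facet_names") <- facet_names
  prov
}
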