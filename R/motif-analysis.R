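#' Relative motif contributions per species (eta)
#'
#' Normalizes each species' occurrence probabilities across motifs:
#' `eta_kg = theta_kg / sum_k' theta_k'g`. For two motifs this is the
#' familiar relative-affinity summary (eta = 1 in one motif and 0 in the
#' other marks exclusive membership); the same normalization applies for any
#' K. Species whose occurrence probabilities are zero in every motif have no
#' defined eta and are masked.
#'
#' @param theta K x G matrix of occurrence probabilities in \[0, 1\].
#' @param taxon_ids optional taxon labels (default from `colnames(theta)`).
#' @return An object of class `eta_matrix`: list with `eta` (K x G; columns
#'   sum to 1 where defined, NA where not), `taxon_ids` and `defined_mask`.
#' @examples
#' relative_contributions(rbind(c(0.5, 0.4), c(0, 0.1)))$eta
#' @export
relative_contributions <- function(theta, taxon_ids = NULL) {
  theta <- as.matrix(theta)
  if (any(theta < 0) || any(theta > 1)) stop("theta entries must be in [0, 1]")
  taxon_ids <- as.character(taxon_ids %||% colnames(theta) %||%
    paste0("taxon_", seq_len(ncol(theta))))
  tot <- colSums(theta)
  defined <- tot > 0
  eta <- sweep(theta, 2L, ifelse(defined, tot, NA_real_), "/")
  colnames(eta) <- taxon_ids
  structure(
    list(eta = eta, taxon_ids = taxon_ids, defined_mask = defined),
    class = "eta_matrix"
  )
}

#' Classify species by relative motif contribution
#'
#' A species is labeled `"mixed"` iff any of its eta values lies strictly
#' inside `(lower, upper)`; otherwise it is assigned to the motif with the
#' largest eta. Species with undefined eta (zero occurrence probability in
#' every motif) are labeled `"undefined"`. The default interval (0.01, 0.9)
#' captures boundary-spanning species whose affinity is split across motifs.
#'
#' @param eta an `eta_matrix` from [relative_contributions()].
#' @param lower,upper thresholds with `0 < lower < upper < 1`.
#' @return An object of class `species_classification`: data frame with
#'   columns `taxon_id` and `label` (a motif index as `"motif_<k>"`,
#'   `"mixed"`, or `"undefined"`), with the thresholds attached as
#'   attributes.
#' @export
classify_species <- function(eta, lower = 0.01, upper = 0.9) {
  stopifnot(inherits(eta, "eta_matrix"))
  if (!(0 < lower && lower < upper && upper < 1)) {
    stop("thresholds must satisfy 0 < lower < upper < 1")
  }
  G <- length(eta$taxon_ids)
  label <- character(G)
  for (g in seq_len(G)) {
    if (!eta$defined_mask[g]) {
      label[g] <- "undefined"
      next
    }
    e <- eta$eta[, g]
    if (any(e > lower & e < upper)) {
      label[g] <- "mixed"
    } else {
      label[g] <- paste0("motif_", which.max(e))
    }
  }
  out <- data.frame(taxon_id = eta$taxon_ids, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "lower") <- lower
  attr(out, "upper") <- upper
  class(out) <- c("species_classification", "data.frame")
  out
}

# KL divergence between Bernoulli(p) and Bernoulli(q); infinite when q is
# degenerate and p disagrees, which correctly ranks exclusive species first.
bernoulli_kl <- function(p, q) {
  term <- function(a, b) {
    out <- numeric(length(a))
    nz <- a > 0
    out[nz] <- a[nz] * (log(a[nz]) - log(b[nz]))
    out[nz & b == 0] <- Inf
    out
  }
  term(p, q) + term(1 - p, 1 - q)
}

#' Top distinguishing species per motif
#'
#' Scores each species for each motif by how sharply its occurrence
#' probability under that motif differs from its probability under the most
#' similar other motif: `s_kg = min over k' != k of
#' KL(Bernoulli(theta_kg) || Bernoulli(theta_k'g))`. Species occurring only
#' under one motif receive infinite scores and rank first. Ties are broken
#' by taxon id. For K = 1 the score falls back to the occurrence probability
#' itself.
#'
#' @param theta K x G occurrence-probability matrix.
#' @param top_n number of species per motif (values above G return all G).
#' @param taxon_ids optional taxon labels.
#' @return A list of length K; element k is a data frame (`taxon_id`,
#'   `score`) of the `top_n` highest-scoring species for motif k, best first.
#'   The score definition is attached as attribute `score_method`.
#' @export
extract_top_features <- function(theta, top_n, taxon_ids = NULL) {
  stopifnot(top_n >= 1L)
  theta <- as.matrix(theta)
  K <- nrow(theta); G <- ncol(theta)
  taxon_ids <- as.character(taxon_ids %||% colnames(theta) %||%
    paste0("taxon_", seq_len(G)))
  top_n <- min(as.integer(top_n), G)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    if (K == 1L) {
      score <- theta[1L, ]
    } else {
      others <- setdiff(seq_len(K), k)
      kl <- vapply(others, function(k2) {
        bernoulli_kl(theta[k, ], theta[k2, ])
      }, numeric(G))
      score <- if (length(others) == 1L) as.numeric(kl) else
        apply(kl, 1L, min)
    }
    ord <- order(-score, taxon_ids)
    out[[k]] <- data.frame(
      taxon_id = taxon_ids[ord][seq_len(top_n)],
      score = score[ord][seq_len(top_n)],
      stringsAsFactors = FALSE
    )
  }
  names(out) <- paste0("motif_", seq_len(K))
  attr(out, "score_method") <-
    "min pairwise KL(Bernoulli(theta_kg) || Bernoulli(theta_k'g)) over k' != k"
  out
}

#' Mean and SD of motif composition over a set of sites
#'
#' Column-wise sample mean and sample standard deviation (denominator n - 1)
#' of the mixing-proportion rows for the requested sites; used to summarize
#' the average composition of a region. A single-site mask reports SD = 0.
#'
#' @param fit a `motif_fit`.
#' @param site_mask nonempty character vector of site ids (a subset of the
#'   fit's sites).
#' @return A data frame with columns `motif`, `mean`, `sd` and attribute
#'   `n_sites`.
#' @export
composition_summary <- function(fit, site_mask) {
  stopifnot(inherits(fit, "motif_fit"))
  if (length(site_mask) == 0L) stop("empty site mask")
  idx <- match(site_mask, fit$site_ids)
  if (anyNA(idx)) {
    stop("unknown site ids: ",
         paste(utils::head(site_mask[is.na(idx)], 5L), collapse = ", "))
  }
  w <- fit$omega[idx, , drop = FALSE]
  sds <- if (nrow(w) == 1L) {
    message("single-site mask: SD reported as 0")
    rep(0, ncol(w))
  } else {
    apply(w, 2L, stats::sd)
  }
  out <- data.frame(
    motif = paste0("motif_", seq_len(fit$K)),
    mean = colMeans(w), sd = sds
  )
  attr(out, "n_sites") <- nrow(w)
  out
}

#' Beta diversity between two motifs' species sets
#'
#' For a two-motif fit, builds the species sets exclusively affiliated with
#' each motif (classification labels from [classify_species()] at the given
#' thresholds; mixed and undefined species are excluded), then reports
#' theta-weighted Bray-Curtis dissimilarity between the motifs' occurrence
#' weights over the classified species, unweighted UniFrac between the two
#' sets on the tree, and Faith's / standardized PD per set.
#'
#' @param theta K x G occurrence-probability matrix with K = 2.
#' @param eta the matching `eta_matrix`.
#' @param tree an [ape::phylo] tree whose tips cover the classified taxa.
#' @param lower,upper classification thresholds.
#' @param n_null null draws for [standardized_pd()].
#' @param seed RNG seed for the PD null.
#' @return A list with `bray_curtis`, `unifrac`, and per-motif data frame
#'   `pd` (columns `motif`, `n`, `faiths_pd`, `standardized_pd`), plus the
#'   classification used.
#' @export
motif_beta_diversity <- function(theta, eta, tree, lower = 0.01, upper = 0.9,
                                 n_null = 1000L, seed = 1L) {
  theta <- as.matrix(theta)
  if (nrow(theta) != 2L) {
    stop("pairwise motif comparison requires exactly 2 motifs")
  }
  cls <- classify_species(eta, lower = lower, upper = upper)
  set_1 <- cls$taxon_id[cls$label == "motif_1"]
  set_2 <- cls$taxon_id[cls$label == "motif_2"]
  if (length(set_1) < 1L || length(set_2) < 1L) {
    stop("each motif needs at least one exclusively affiliated species")
  }
  both <- c(set_1, set_2)
  idx <- match(both, eta$taxon_ids)
  bc <- bray_curtis_weighted(theta[1L, idx], theta[2L, idx])
  missing <- setdiff(both, tree$tip.label)
  if (length(missing)) {
    stop("classified taxa missing from the tree: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  uf <- unifrac(tree, set_1, set_2)
  pd <- do.call(rbind, lapply(seq_len(2L), function(k) {
    set <- if (k == 1L) set_1 else set_2
    z <- standardized_pd(tree, set, n_null = n_null, seed = seed + k)
    data.frame(
      motif = paste0("motif_", k), n = length(set),
      faiths_pd = z$pd_obs, standardized_pd = z$z
    )
  }))
  list(bray_curtis = bc, unifrac = uf, pd = pd, classification = cls)
}
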