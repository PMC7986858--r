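#' Define a synthetic archipelago scenario
#'
#' Parameters for a lattice of 1-degree map cells crossed by a biotic
#' transition: K latent biotas mix across a boundary with controllable
#' steepness, species carry motif-specific occurrence probabilities with
#' optional endemics and boundary-crossing "transgressors", and an
#' ultrametric pure-birth phylogeny associates clades with motifs to a
#' controllable degree. The defaults describe the reference study condition
#' used throughout the package's tests: a 10 x 20 grid (200 cells), 60
#' species, two biotas separated by a sharp longitudinal transition
#' (steepness 10 at the grid midline), high occurrence contrast (0.9), a
#' small fraction (5%) of transgressor species present in both biotas, and
#' fully motif-associated clades.
#'
#' @param n_rows,n_cols grid dimensions (1-degree cell spacing).
#' @param K_true number of latent biotas.
#' @param G number of species.
#' @param boundary_lon longitude of the transition midline (default grid
#'   center); used when `K_true = 2`.
#' @param steepness logistic slope of the transition (per degree); larger is
#'   sharper.
#' @param contrast gap between within-motif and out-of-motif occurrence
#'   probabilities, in (0, 1]: home probability `0.1 + 0.8 * contrast`, away
#'   probability `0.08 * (1 - contrast)`.
#' @param endemic_fraction fraction of species restricted to a narrow
#'   longitudinal band of cells.
#' @param transgressor_fraction fraction of species given home-level
#'   occurrence probability in two motifs.
#' @param clade_assoc probability that a species is placed inside its home
#'   motif's clade on the simulated tree (1 = motifs monophyletic).
#' @param birth_rate speciation rate of the pure-birth tree.
#' @param n_deep_cross number of deep boundary-crossing clades: blocks of one
#'   motif's species grafted as a monophyletic sister clade inside another
#'   motif's subtree.
#' @param tree_depth depth the simulated tree is rescaled to (time units),
#'   so time slices at 5..50 are meaningful.
#' @param endemic_band_width width (cells) of endemic longitude bands.
#' @param seed integer seed making the whole scenario reproducible.
#' @return A list of class `archipelago_scenario`.
#' @export
archipelago_scenario <- function(n_rows = 10L, n_cols = 20L, K_true = 2L,
                                 G = 60L, boundary_lon = NULL, steepness = 10,
                                 contrast = 0.9, endemic_fraction = 0,
                                 transgressor_fraction = 0.05,
                                 clade_assoc = 1, birth_rate = 0.1,
                                 n_deep_cross = 0L, tree_depth = 50,
                                 endemic_band_width = 3L, seed = 1L) {
  stopifnot(
    n_rows * n_cols >= 2L, K_true >= 1L, G >= K_true, steepness >= 0,
    contrast > 0, contrast <= 1,
    endemic_fraction >= 0, endemic_fraction <= 1,
    transgressor_fraction >= 0, transgressor_fraction <= 1,
    endemic_fraction + transgressor_fraction <= 1,
    clade_assoc >= 0, clade_assoc <= 1, birth_rate > 0, tree_depth > 0
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      K_true = as.integer(K_true), G = as.integer(G),
      boundary_lon = boundary_lon %||% (n_cols / 2), steepness = steepness,
      contrast = contrast, endemic_fraction = endemic_fraction,
      transgressor_fraction = transgressor_fraction,
      clade_assoc = clade_assoc, birth_rate = birth_rate,
      n_deep_cross = as.integer(n_deep_cross), tree_depth = tree_depth,
      endemic_band_width = as.integer(endemic_band_width),
      seed = as.integer(seed)
    ),
    class = "archipelago_scenario"
  )
}

#' Grid-cell center coordinates for a scenario
#'
#' @param scenario an [archipelago_scenario].
#' @return Data frame with `site_id`, `lat`, `lon` (cell centers at
#'   half-degree offsets), in row-major order.
#' @export
scenario_grid <- function(scenario) {
  grid <- expand.grid(
    col = seq_len(scenario$n_cols), row = seq_len(scenario$n_rows)
  )
  data.frame(
    site_id = sprintf("cell_%03d", seq_len(nrow(grid))),
    lat = grid$row - 0.5, lon = grid$col - 0.5
  )
}

#' Spatial field of mixing proportions
#'
#' For two biotas, a logistic east-west transition:
#' `omega_2 = 1 / (1 + exp(-steepness * (lon - boundary_lon)))` and
#' `omega_1 = 1 - omega_2`, so the cell at the boundary is an even mixture
#' and steepness controls how abrupt the turnover is. For more than two
#' biotas the field is a row-normalized set of Gaussian bumps centered on
#' anchors spread along the longitude axis (the logistic construction does
#' not generalize).
#'
#' @param grid data frame with `lat`, `lon` per cell (see [scenario_grid()]).
#' @param boundary_lon transition midline (degrees), used for `K_true = 2`.
#' @param steepness logistic slope per degree.
#' @param K_true number of biotas.
#' @return N x K_true matrix with rows on the simplex.
#' @export
simulate_omega_field <- function(grid, boundary_lon, steepness, K_true = 2L) {
  N <- nrow(grid)
  if (K_true == 1L) return(matrix(1, N, 1L))
  if (K_true == 2L) {
    w2 <- 1 / (1 + exp(-steepness * (grid$lon - boundary_lon)))
    return(unname(cbind(1 - w2, w2)))
  }
  lon_span <- max(grid$lon) - min(grid$lon)
  anchors_lon <- min(grid$lon) + (seq_len(K_true) - 0.5) * lon_span / K_true
  anchor_lat <- mean(grid$lat)
  sigma <- max(lon_span / (2 * K_true), 1)
  w <- vapply(seq_len(K_true), function(k) {
    d2 <- (grid$lon - anchors_lon[k])^2 + (grid$lat - anchor_lat)^2
    exp(-d2 / (2 * sigma^2))
  }, numeric(N))
  w / rowSums(w)
}

#' Motif-specific species occurrence probabilities
#'
#' Assigns each species a home motif (balanced across motifs), giving it
#' occurrence probability `0.1 + 0.8 * contrast` under that motif and
#' `0.08 * (1 - contrast)` under the others. A random `transgressor_fraction`
#' of species receive home-level probability in a second motif as well
#' (emulating boundary-crossing species); a random `endemic_fraction` are
#' tagged endemic — their probabilities are unchanged here, but
#' [simulate_scenario()] restricts their realized ranges to a narrow
#' longitude band.
#'
#' @param K_true number of motifs.
#' @param G number of species.
#' @param contrast occurrence contrast in (0, 1].
#' @param endemic_fraction,transgressor_fraction role fractions, summing to
#'   at most 1.
#' @param seed RNG seed.
#' @return K_true x G matrix with attributes `home` (home motif per
#'   species), `role` (`"regular"`, `"endemic"` or `"transgressor"`) and
#'   `second_motif` (NA except for transgressors).
#' @export
simulate_theta <- function(K_true, G, contrast, endemic_fraction = 0,
                           transgressor_fraction = 0, seed = 1L) {
  stopifnot(endemic_fraction + transgressor_fraction <= 1)
  home_p <- 0.1 + 0.8 * contrast
  away_p <- 0.08 * (1 - contrast)
  with_seed(seed, {
    home <- sample(rep_len(seq_len(K_true), G))
    theta <- matrix(away_p, K_true, G)
    theta[cbind(home, seq_len(G))] <- home_p
    role <- rep("regular", G)
    n_trans <- round(transgressor_fraction * G)
    n_end <- round(endemic_fraction * G)
    special <- sample.int(G, n_trans + n_end)
    trans <- special[seq_len(n_trans)]
    endem <- special[setdiff(seq_along(special), seq_len(n_trans))]
    role[trans] <- "transgressor"
    role[endem] <- "endemic"
    second <- rep(NA_integer_, G)
    if (K_true >= 2L) {
      for (g in trans) {
        second[g] <- resample(setdiff(seq_len(K_true), home[g]), 1L)
        theta[second[g], g] <- home_p
      }
    }
    colnames(theta) <- sprintf("sp_%03d", seq_len(G))
    structure(theta, home = home, role = role, second_motif = second)
  })
}

# Newick fragment for a pure-birth subtree on `tips`, rescaled to `depth`.
# A single tip is encoded as a bare leaf whose branch equals `depth`.
block_newick <- function(tips, depth, birth_rate) {
  if (length(tips) == 1L) {
    return(sprintf("%s:%.10g", tips, depth))
  }
  st <- ape::rphylo(length(tips), birth = birth_rate, death = 0)
  st$edge.length <- st$edge.length *
    (depth / max(ape::node.depth.edgelength(st)))
  st$tip.label <- sample(tips)
  sub(";$", "", ape::write.tree(st, digits = 12))
}

#' Simulate a motif-structured ultrametric phylogeny
#'
#' Grows a pure-birth tree of G tips in which species motifs are
#' phylogenetically clustered to a controllable degree: each species is
#' placed inside its home motif's clade with probability `clade_assoc` and
#' in a random clade otherwise, so `clade_assoc = 1` makes every motif
#' monophyletic and `clade_assoc = 0` interleaves labels freely. Optionally,
#' `n_deep_cross` whole blocks of one motif's species are grafted as deep
#' monophyletic sister clades inside another motif's subtree, emulating
#' lineage-level affinity that crosses the boundary. The tree is rescaled to
#' the requested total depth.
#'
#' @param G number of tips.
#' @param clade_assoc clade-motif association probability in \[0, 1\].
#' @param birth_rate speciation rate.
#' @param motif_labels integer vector (length G) of home motifs; tip g is
#'   named `names(motif_labels)[g]` (or `sp_<g>`).
#' @param seed RNG seed.
#' @param depth total tree depth after rescaling (time units).
#' @param n_deep_cross number of deep boundary-crossing clades.
#' @return An ultrametric [ape::phylo] tree with G tips.
#' @export
simulate_tree <- function(G, clade_assoc, birth_rate, motif_labels,
                          seed = 1L, depth = 50, n_deep_cross = 0L) {
  stopifnot(length(motif_labels) == G)
  tip_names <- names(motif_labels) %||% sprintf("sp_%03d", seq_len(G))
  K <- max(motif_labels)
  with_seed(seed, {
    placement <- vapply(seq_len(G), function(g) {
      if (stats::runif(1) <= clade_assoc) motif_labels[g]
      else sample.int(K, 1L)
    }, numeric(1))
    groups <- split(tip_names, factor(placement, levels = seq_len(K)))
    # peel off deep-crossing blocks: ~25% of a donor motif's block, moved
    # into another group's subtree as its own clade
    cross <- vector("list", K)
    for (i in seq_len(n_deep_cross)) {
      sizes <- lengths(groups)
      donors <- which(sizes >= 4L)
      if (length(donors) == 0L || K < 2L) break
      d <- donors[sample.int(length(donors), 1L)]
      take <- max(2L, floor(sizes[d] / 4))
      moved <- sample(groups[[d]], take)
      groups[[d]] <- setdiff(groups[[d]], moved)
      host <- resample(setdiff(seq_len(K), d), 1L)
      cross[[host]] <- c(cross[[host]], list(moved))
    }
    keep <- which(lengths(groups) > 0L | lengths(cross) > 0L)
    group_depth <- 0.8 * depth
    block_depth <- 0.55 * depth
    group_strs <- vapply(keep, function(k) {
      blocks <- c(
        if (length(groups[[k]])) list(groups[[k]]) else NULL,
        cross[[k]]
      )
      if (length(blocks) == 1L) {
        paste0(block_newick(blocks[[1L]], group_depth, birth_rate),
               ":", format(depth - group_depth, digits = 10))
      } else {
        inner <- paste(vapply(blocks, function(b) {
          paste0(block_newick(b, block_depth, birth_rate),
                 ":", format(group_depth - block_depth, digits = 10))
        }, character(1L)), collapse = ",")
        paste0("(", inner, "):", format(depth - group_depth, digits = 10))
      }
    }, character(1L))
    txt <- if (length(group_strs) == 1L) {
      # single clade: stretch it to the full depth
      g <- keep[1L]
      blocks <- c(
        if (length(groups[[g]])) list(groups[[g]]) else NULL, cross[[g]]
      )
      if (length(blocks) == 1L) {
        paste0("(", block_newick(blocks[[1L]], depth, birth_rate), ");")
      } else {
        paste0("(", paste(vapply(blocks, function(b) {
          paste0(block_newick(b, block_depth, birth_rate),
                 ":", format(depth - block_depth, digits = 10))
        }, character(1L)), collapse = ","), ");")
      }
    } else {
      paste0("(", paste(group_strs, collapse = ","), ");")
    }
    read_newick(text = txt)
  })
}

#' Draw a presence-absence matrix from mixing proportions and motif
#' occurrence probabilities
#'
#' Each cell is an independent Bernoulli draw with success probability
#' `p_ng = sum_k omega_nk * theta_kg`.
#'
#' @param omega N x K mixing matrix (rows on the simplex).
#' @param theta K x G occurrence-probability matrix.
#' @param seed RNG seed.
#' @param site_ids,coords optional site labels and coordinates passed to
#'   [presence_absence()].
#' @return A [presence_absence] object.
#' @export
sample_presence <- function(omega, theta, seed = 1L, site_ids = NULL,
                            coords = NULL) {
  omega <- as.matrix(omega); theta <- as.matrix(theta)
  stopifnot(ncol(omega) == nrow(theta))
  p <- omega %*% theta
  m <- with_seed(seed, {
    matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p))
  })
  presence_absence(m, site_ids = site_ids, taxon_ids = colnames(theta),
                   coords = coords)
}

#' Simulate a full archipelago scenario
#'
#' Composes the spatial mixing field, motif occurrence probabilities, the
#' motif-structured tree and the Bernoulli presence draws into a dataset
#' plus its complete ground truth. Endemic species (if any) have their
#' realized presences restricted to a random contiguous longitude band of
#' `endemic_band_width` cells, mimicking island endemism; this masking acts
#' on the sampled matrix, outside the mixed-membership factorization itself.
#' Deterministic given `scenario$seed`.
#'
#' @param scenario an [archipelago_scenario].
#' @return A list with `data` (a [presence_absence] with coordinates) and
#'   `truth` (list: `omega`, `theta`, `tree`, `home`, `role`,
#'   `endemic_bands`, `scenario`).
#' @examples
#' sim <- simulate_scenario(archipelago_scenario(n_rows = 4, n_cols = 8,
#'                                               G = 20, seed = 42))
#' dim(sim$data)
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "archipelago_scenario"))
  grid <- scenario_grid(scenario)
  omega <- simulate_omega_field(grid, scenario$boundary_lon,
                                scenario$steepness, scenario$K_true)
  theta <- simulate_theta(
    scenario$K_true, scenario$G, scenario$contrast,
    scenario$endemic_fraction, scenario$transgressor_fraction,
    seed = scenario$seed + 1L
  )
  home <- attr(theta, "home")
  role <- attr(theta, "role")
  tree <- simulate_tree(
    scenario$G, scenario$clade_assoc, scenario$birth_rate,
    stats::setNames(home, colnames(theta)),
    seed = scenario$seed + 2L, depth = scenario$tree_depth,
    n_deep_cross = scenario$n_deep_cross
  )
  pa <- sample_presence(omega, theta, seed = scenario$seed + 3L,
                        site_ids = grid$site_id, coords = grid)
  bands <- NULL
  endems <- which(role == "endemic")
  if (length(endems)) {
    w <- scenario$endemic_band_width
    starts <- with_seed(scenario$seed + 4L, {
      sample.int(max(scenario$n_cols - w + 1L, 1L), length(endems),
                 replace = TRUE)
    })
    bands <- data.frame(
      taxon_id = colnames(theta)[endems],
      lon_min = starts - 1, lon_max = starts - 1 + w
    )
    m <- pa$m
    for (i in seq_along(endems)) {
      outside <- grid$lon < bands$lon_min[i] | grid$lon > bands$lon_max[i]
      m[outside, endems[i]] <- 0L
    }
    pa <- presence_absence(m, site_ids = pa$site_ids,
                           taxon_ids = pa$taxon_ids, coords = grid)
  }
  list(
    data = pa,
    truth = list(omega = omega, theta = theta, tree = tree, home = home,
                 role = role, endemic_bands = bands, scenario = scenario)
  )
}
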