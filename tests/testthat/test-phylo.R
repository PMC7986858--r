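test_that("newick input validates and round-trips", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tree_depth(tr), 2)
  expect_true(is_ultrametric_tree(tr))
  expect_error(read_newick(text = "((A:1,B:1):1,C:2"), "malformed|Newick")

  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.nwk")
  write_newick(tr, path)
  tr2 <- read_newick(path)
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE,
                                   tolerance = 1e-9))
})

test_that("pruning keeps path lengths and reports missing taxa", {
  tr <- caterpillar3()
  same <- prune_to_taxa(tr, c("A", "B", "C"))
  expect_equal(sort(same$tip.label), sort(tr$tip.label))

  two <- prune_to_taxa(tr, c("A", "C"))
  d <- ape::node.depth.edgelength(two)[1:2]
  expect_equal(unname(d), c(2, 2))

  one <- prune_to_taxa(tr, "A")
  expect_equal(one$tip.label, "A")
  expect_equal(tree_depth(one), 2)

  expect_warning(pr <- prune_to_taxa(tr, c("A", "Z")), "absent")
  expect_equal(attr(pr, "missing_taxa"), "Z")
  expect_error(prune_to_taxa(tr, "Z"), "no requested taxa")
})

test_that("time slices follow the half-open branch convention", {
  tr <- caterpillar3()
  s0 <- time_slice(tr, 0)
  expect_equal(sort(s0$lineage_ids), c("A", "B", "C"))
  expect_equal(s0$members[["A"]], "A")

  s15 <- time_slice(tr, 1.5)
  expect_equal(s15$n_lineages, 2L)
  expect_true(any(vapply(s15$members, setequal, logical(1), c("A", "B"))))

  # boundary: the internal branch spans [1, 2) so T = 1 keeps {A,B} merged
  s1 <- time_slice(tr, 1.0)
  expect_equal(s1$n_lineages, 2L)
  expect_true(any(vapply(s1$members, setequal, logical(1), c("A", "B"))))

  expect_error(time_slice(tr, 2), "T must")
  bad <- read_newick(text = "((A:1,B:3):1,C:2);")
  expect_error(time_slice(bad, 1), "ultrametric")
})

test_that("slice laws hold on random ultrametric trees", {
  for (seed in 1:8) {
    tr <- random_ultrametric_tree(sample(5:20, 1), seed)
    depth <- tree_depth(tr)
    counts <- vapply(seq(0, 0.95, by = 0.19) * depth, function(T) {
      sl <- time_slice(tr, T)
      members <- unlist(sl$members, use.names = FALSE)
      expect_equal(sort(members), sort(tr$tip.label)) # partition
      sl$n_lineages
    }, integer(1))
    expect_true(all(diff(counts) <= 0))               # non-increasing in T
    expect_equal(counts[1], length(tr$tip.label))     # T = 0 identity
  }
})

test_that("lineage presences are unions of member species ranges", {
  tr <- caterpillar3()
  m <- rbind(c(1L, 0L, 0L), c(0L, 1L, 1L), c(0L, 0L, 0L))
  pa <- presence_absence(m, site_ids = paste0("s", 1:3),
                         taxon_ids = c("A", "B", "C"))
  sl <- time_slice(tr, 1.5)
  lp <- lineage_presence(pa, sl)
  ab <- which(vapply(sl$members, setequal, logical(1), c("A", "B")))
  expect_equal(unname(lp$m[, ab]), c(1L, 1L, 0L))     # union of A and B
  cid <- which(vapply(sl$members, setequal, logical(1), "C"))
  expect_equal(unname(lp$m[, cid]), unname(m[, 3]))   # singleton copies row

  lp0 <- lineage_presence(pa, time_slice(tr, 0))
  expect_equal(unname(lp0$m[, match(c("A", "B", "C"), lp0$taxon_ids)]),
               unname(m))

  pa_small <- presence_absence(m[, 1:2, drop = FALSE],
                               site_ids = paste0("s", 1:3),
                               taxon_ids = c("A", "B"))
  expect_error(lineage_presence(pa_small, sl), "missing")
})

test_that("Faith's PD uses the rooted spanning subtree", {
  tr <- balanced4()
  expect_equal(faiths_pd(tr, c("A", "B")), 3)
  expect_equal(faiths_pd(tr, tr$tip.label), 6)
  expect_equal(faiths_pd(caterpillar3(), "A"), 2)
  expect_error(faiths_pd(tr, character(0)), "empty")
  expect_error(faiths_pd(tr, "nope"), "unknown")

  # monotone under adding taxa; agrees with picante's rooted PD
  for (seed in 1:5) {
    tr2 <- random_ultrametric_tree(10, seed + 40)
    set.seed(seed)
    taxa <- sample(tr2$tip.label, 4)
    pd1 <- faiths_pd(tr2, taxa)
    expect_gte(faiths_pd(tr2, c(taxa, sample(setdiff(tr2$tip.label, taxa), 1))),
               pd1)
    comm <- matrix(as.integer(tr2$tip.label %in% taxa), 1,
                   dimnames = list("s", tr2$tip.label))
    expect_equal(pd1, picante::pd(comm, tr2, include.root = TRUE)$PD,
                 tolerance = 1e-9)
  }
})

test_that("standardized PD matches exact enumeration and handles degeneracy", {
  tr <- balanced8()
  # all tips: degenerate null
  z_all <- standardized_pd(tr, tr$tip.label, n_null = 100, seed = 1)
  expect_true(z_all$degenerate_null)
  expect_equal(z_all$z, 0)
  # star tree: any subset of fixed size has identical PD
  star <- read_newick(text = "(A:1,B:1,C:1,D:1,E:1);")
  z_star <- standardized_pd(star, c("A", "C"), n_null = 200, seed = 2)
  expect_equal(z_star$z, 0)
  # clade subset: z < 0 and close to the exact enumeration oracle
  sixtip <- read_newick(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")
  z <- standardized_pd(sixtip, c("A", "B", "C"), n_null = 100000, seed = 3)
  expect_lt(z$z, 0)
  expect_equal(z$z, oracle_standardized_pd(sixtip, c("A", "B", "C")),
               tolerance = 0.05)
  expect_error(standardized_pd(tr, "A", n_null = 1), "n_null")
})

test_that("unifrac matches hand values and the brute-force oracle", {
  tr <- balanced4()
  expect_equal(unifrac(tr, c("A", "B"), c("C", "D")), 1)
  expect_equal(unifrac(tr, c("A", "B"), c("A", "B")), 0)
  expect_equal(unifrac(caterpillar3(), c("A", "B"), c("B", "C")), 0.6)
  expect_error(unifrac(tr, character(0), "A"), "empty")

  for (seed in 1:5) {
    tr2 <- random_ultrametric_tree(6, seed + 90)
    tips <- tr2$tip.label
    set.seed(seed)
    for (rep in 1:10) {
      a <- sample(tips, sample(1:5, 1))
      b <- sample(tips, sample(1:5, 1))
      expect_equal(unifrac(tr2, a, b), oracle_unifrac(tr2, a, b),
                   tolerance = 1e-12)
      expect_equal(unifrac(tr2, a, b), unifrac(tr2, b, a))
    }
  }
})

test_that("weighted Bray-Curtis follows its closed form", {
  expect_equal(bray_curtis_weighted(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(bray_curtis_weighted(c(0.8, 0.2), c(0.2, 0.8)), 0.6)
  expect_equal(bray_curtis_weighted(c(0.5, 0.1), c(0.5, 0.1)), 0)
  expect_error(bray_curtis_weighted(c(0, 0), c(1, 0)), "all-zero")
  expect_error(bray_curtis_weighted(1, c(1, 0)), "length")
  # cross-check against vegan on random weight vectors
  set.seed(6)
  for (rep in 1:5) {
    a <- runif(10); b <- runif(10)
    expect_equal(bray_curtis_weighted(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b), "bray")),
                 tolerance = 1e-12)
  }
})
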