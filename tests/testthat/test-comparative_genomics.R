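# ANI, maxbit graph, MCL, presence/absence, dendrogram, unique clusters,
# enrichment.

test_that("fragment_genome applies the remainder rule", {
  g <- generate_reference(1, 3060, orf_density = 0, seed = 61)$contigs
  expect_equal(nrow(fragment_genome(g)), 3)
  g2 <- c(c1 = paste(rep("A", 1019), collapse = ""))
  expect_equal(nrow(fragment_genome(g2)), 0)
  # counting oracle on a multi-contig genome
  g3 <- generate_reference(3, 2500, orf_density = 0, seed = 62)$contigs
  expect_equal(nrow(fragment_genome(g3)), sum(nchar(g3) %/% 1020))
  expect_error(fragment_genome(g, fragment_length = 50), ">= 100")
})

test_that("align_fragment finds verbatim and diverged fragments, rejects noise", {
  set.seed(63)
  g <- generate_reference(1, 8000, orf_density = 0, seed = 63)$contigs
  frag <- substr(g[[1]], 2001, 3020)
  h <- align_fragment(frag, g)
  expect_true(h$hit)
  expect_equal(h$identity, 1)
  expect_equal(h$coverage, 1)

  # ~2% substitutions: identity near 0.98
  ch <- strsplit(frag, "")[[1]]
  at <- sample(1020, 20)
  ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  h2 <- align_fragment(paste(ch, collapse = ""), g)
  expect_true(h2$hit)
  expect_equal(h2$identity, 0.98, tolerance = 3 * sqrt(0.02 * 0.98 / 1020) + 0.003)

  # reverse-complement fragment still aligns (minus strand)
  h3 <- align_fragment(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(frag))), g)
  expect_true(h3$hit)
  expect_equal(h3$identity, 1)

  # unrelated random sequence: no seed support, no hit
  unrelated <- generate_reference(1, 2000, orf_density = 0, seed = 64)$contigs
  rand_frag <- substr(generate_reference(1, 2040, orf_density = 0,
                                         seed = 65)$contigs[[1]], 1, 1020)
  expect_false(align_fragment(rand_frag, unrelated)$hit)
})

test_that("compute_ani recovers planted divergence and decreases monotonically", {
  g <- generate_reference(1, 8160, orf_density = 0, seed = 66)$contigs
  expect_equal(compute_ani(g, g)$mean_of_directions, 100)

  anis <- vapply(c(0, 0.01, 0.02, 0.05), function(d) {
    pair <- generate_divergent_pair(g, d, seed = 67)
    compute_ani(pair$genome_a, pair$genome_b)$mean_of_directions
  }, numeric(1))
  expect_equal(anis[1], 100)
  expect_equal(anis[3], 98, tolerance = 0.3 / 98)
  expect_true(all(diff(anis) < 0))
  # d = 0.001 crosses the same-species line (> 98)
  near <- generate_divergent_pair(g, 0.001, seed = 68)
  expect_gt(compute_ani(near$genome_a, near$genome_b)$mean_of_directions, 98)
})

test_that("maxbit graph normalizes by the smaller self-score and keeps the boundary", {
  scores <- data.frame(
    orf_a = c("a", "b", "c", "a", "a", "b"),
    orf_b = c("a", "b", "c", "b", "c", "c"),
    score = c(100, 120, 80, 30, 100, 10)
  )
  g <- build_maxbit_graph(scores, threshold = 0.3)
  e <- g$edges
  # score 30 with self 100/120 -> 0.3, kept at the boundary
  expect_equal(e$weight[e$a == "a" & e$b == "b"], 0.3)
  # identical ORFs: weight capped at 1
  expect_equal(e$weight[e$a == "a" & e$b == "c"], 1)
  # 10 / min(120, 80) = 0.125 < 0.3: dropped
  expect_false(any(e$a == "b" & e$b == "c"))

  expect_error(build_maxbit_graph(scores[scores$orf_a != "c" | scores$orf_b != "c", ]),
               "self-score")

  # brute-force recomputation of the kept-edge set on a random score table
  set.seed(69)
  ids <- paste0("o", 1:8)
  self <- setNames(runif(8, 80, 150), ids)
  pairs <- t(combn(ids, 2))
  sc <- runif(nrow(pairs), 0, 100)
  tab <- rbind(data.frame(orf_a = ids, orf_b = ids, score = unname(self)),
               data.frame(orf_a = pairs[, 1], orf_b = pairs[, 2], score = sc))
  kept <- build_maxbit_graph(tab, 0.3)$edges
  for (i in seq_len(nrow(pairs))) {
    w <- min(1, sc[i] / min(self[pairs[i, 1]], self[pairs[i, 2]]))
    in_graph <- any(kept$a == pairs[i, 1] & kept$b == pairs[i, 2])
    expect_equal(in_graph, w >= 0.3, info = paste(pairs[i, ], collapse = "-"))
  }
})

test_that("mcl_cluster separates disjoint cliques and keeps singletons", {
  ids <- c(paste0("x", 1:4), paste0("y", 1:3), "lone")
  self <- data.frame(orf_a = ids, orf_b = ids, score = 100)
  cliq <- function(members) {
    p <- t(combn(members, 2))
    data.frame(orf_a = p[, 1], orf_b = p[, 2], score = 90)
  }
  g <- build_maxbit_graph(rbind(self, cliq(ids[1:4]), cliq(ids[5:7])))
  cl <- mcl_cluster(g, inflation = 2)
  expect_length(cl$clusters, 3)
  sizes <- sort(lengths(cl$clusters), decreasing = TRUE)
  expect_equal(unname(sizes), c(4, 3, 1))
  expect_setequal(cl$clusters[[1]], ids[1:4])
  expect_equal(unname(cl$membership["lone"]),
               names(cl$clusters)[lengths(cl$clusters) == 1])
})

test_that("MCL output is a partition, relabel-invariant, and matches a naive implementation", {
  set.seed(71)
  n <- 20
  ids <- sprintf("n%02d", 1:n)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < 0.25) adj[i, j] <- adj[j, i] <- runif(1, 0.3, 1)
  }
  edges <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  tab <- rbind(
    data.frame(orf_a = ids, orf_b = ids, score = 1),
    data.frame(orf_a = ids[edges[, 1]], orf_b = ids[edges[, 2]],
               score = adj[edges])
  )
  g <- build_maxbit_graph(tab, threshold = 0.3)
  cl <- mcl_cluster(g, inflation = 2)

  # partition: disjoint cover of all nodes
  members <- unlist(cl$clusters, use.names = FALSE)
  expect_setequal(members, ids)
  expect_equal(anyDuplicated(members), 0)

  # equivalence with the loop-based naive MCL on the same adjacency
  got <- canon_partition(cl$clusters, ids)
  want <- naive_mcl(adj, inflation = 2)
  want <- want[order(vapply(want, `[`, integer(1), 1))]
  expect_equal(got, want)

  # node relabeling permutes but does not change the partition
  perm <- sample(n)
  relab <- setNames(sprintf("m%02d", order(perm)), ids)  # bijection
  tab2 <- tab
  tab2$orf_a <- unname(relab[tab2$orf_a])
  tab2$orf_b <- unname(relab[tab2$orf_b])
  cl2 <- mcl_cluster(build_maxbit_graph(tab2, 0.3), inflation = 2)
  back <- lapply(cl2$clusters, function(g2) sort(names(relab)[match(g2, relab)]))
  expect_setequal(
    unname(vapply(back, paste, "", collapse = ",")),
    unname(vapply(lapply(cl$clusters, sort), paste, "", collapse = ",")))
})

test_that("presence_absence reflects cluster membership per MAG", {
  clusters <- list(GC_1 = c("a1", "b1"), GC_2 = c("a2"), GC_3 = c("b2", "c1"))
  o2m <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  pa <- presence_absence(clusters, o2m)
  expect_equal(unname(pa["GC_1", ]), c(1, 1, 0))
  expect_equal(unname(pa["GC_2", ]), c(1, 0, 0))
  expect_error(presence_absence(clusters, o2m[-1]), "not assigned")
  expect_error(presence_absence(list(), o2m), "no gene clusters")
})

test_that("dendrogram topology and merge heights match a brute-force agglomeration", {
  # forced topology: A and B share everything, C shares nothing
  m <- cbind(A = c(1, 1, 1, 0), B = c(1, 1, 1, 0), C = c(0, 0, 0, 1))
  rownames(m) <- paste0("gc", 1:4)
  dn <- cluster_dendrogram(m)
  expect_equal(dn$hclust$height[1], 0)  # identical profiles merge first at 0
  tree <- ape::read.tree(text = dn$newick)
  ab <- ape::getMRCA(tree, c("A", "B"))
  expect_false(ape::getMRCA(tree, c("A", "C")) == ab)  # ((A,B),C)

  set.seed(72)
  m2 <- matrix(rbinom(240, 1, 0.5), nrow = 40, ncol = 6,
               dimnames = list(paste0("gc", 1:40), paste0("MAG", 1:6)))
  dn2 <- cluster_dendrogram(m2)
  dmat <- as.matrix(dist(t(m2)))
  expect_equal(sort(dn2$hclust$height), naive_complete_heights(dmat))

  expect_error(cluster_dendrogram(m[, 1, drop = FALSE]), "at least 2")
})

test_that("uniquely_shared matches a brute-force row scan", {
  pan <- generate_pangenome(n_mags = 6, n_core = 40, n_accessory = 6,
                            focal_pair_unique = 12, seed = 73)
  u <- uniquely_shared(pan$matrix, pan$truth$focal_mags)
  expect_setequal(u, pan$truth$unique_clusters)

  set.seed(74)
  m <- matrix(rbinom(300, 1, 0.5), nrow = 60, ncol = 5,
              dimnames = list(paste0("gc", 1:60), paste0("M", 1:5)))
  focal <- c("M1", "M3")
  got <- uniquely_shared(m, focal)
  want <- rownames(m)[apply(m, 1, function(r) {
    all(r[focal] == 1) && all(r[setdiff(colnames(m), focal)] == 0)
  })]
  expect_setequal(got, want)

  # disjoint focal sets yield disjoint results
  got2 <- uniquely_shared(m, c("M2", "M4"))
  expect_length(intersect(got, got2), 0)

  expect_error(uniquely_shared(m, character(0)), "empty")
  expect_error(uniquely_shared(m, colnames(m)), "proper subset")
})

test_that("cog_enrichment flags planted categories and spares flat ones", {
  pan <- generate_pangenome(n_mags = 6, n_core = 400, n_accessory = 30,
                            focal_pair_unique = 100, enriched_category = "M",
                            enrichment_strength = 0.5,
                            background_frequency = 0.1, seed = 75)
  focal <- unname(pan$cog_labels[pan$truth$unique_clusters])
  bg <- unname(pan$cog_labels)
  enr <- cog_enrichment(focal, bg, repetitions = 500, sample_size = 200,
                        seed = 76)
  row <- enr[enr$category == "M", ]
  expect_true(row$enriched_99)
  expect_gt(row$achieved_confidence, 0.99)

  expect_error(cog_enrichment(character(0), bg), "empty")
  expect_error(cog_enrichment(focal, bg, sample_size = 1e6), "exceeds")

  # multi-letter annotations are split per letter
  enr2 <- cog_enrichment(c("MT", "M", "T"), rep(c("M", "T", "C"), 40),
                         repetitions = 50, sample_size = 30, seed = 77)
  expect_equal(enr2$focal_proportion[enr2$category == "M"], 2 / 3)
  expect_equal(enr2$focal_proportion[enr2$category == "T"], 2 / 3)
})
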