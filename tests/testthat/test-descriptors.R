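# Topological descriptor engine: worked small-molecule examples frozen from
# hand/brute-force computation, plus randomized oracle comparisons.

test_that("average connectivity index matches hand-derived chain values", {
  # pentane: single 5-vertex path, degrees 1,2,2,2,1 -> 1/sqrt(8)
  expect_equal(avg_connectivity_index(build_graph("CCCCC"), 4), 1 / sqrt(8))
  # ethane: one edge, both degrees 1
  expect_equal(avg_connectivity_index(build_graph("CC"), 1), 1)
  # butane has no 5-vertex path
  expect_equal(avg_connectivity_index(build_graph("CCCC"), 4), 0)
  # order 0: mean of delta^-1/2
  expect_equal(avg_connectivity_index(build_graph("CCC"), 0),
               mean(c(1, 2, 1)^-0.5))
})

test_that("eccentricity dispersion matches hand-derived values", {
  # pentane path: eccentricities 4,3,2,3,4, mean 3.2
  expect_equal(eccentric_deviation(build_graph("CCCCC")),
               mean(abs(c(4, 3, 2, 3, 4) - 3.2)))
  expect_equal(eccentric_deviation(build_graph("C1CCCCC1")), 0)
  expect_equal(eccentric_deviation(build_graph("C")), 0)
})

test_that("augmented edge-adjacency eigenvalues follow the padding and closed forms", {
  # ethane: single bond -> 1x1 matrix holding its order
  expect_equal(augmented_edge_adjacency_eig(build_graph("CC"), 1), 1)
  # propane: [[1,1],[1,1]] -> eigenvalues 2, 0
  expect_equal(augmented_edge_adjacency_eig(build_graph("CCC"), 1), 2)
  expect_equal(augmented_edge_adjacency_eig(build_graph("CCC"), 2), 0,
               tolerance = 1e-12)
  # fewer bonds than k -> 0 by convention
  expect_equal(augmented_edge_adjacency_eig(build_graph("CCCCCC"), 12), 0)
  # double bond enters the diagonal: ethene 1x1 matrix [2]
  expect_equal(augmented_edge_adjacency_eig(build_graph("C=C"), 1), 2)
})

test_that("autocorrelation descriptors follow the stated zero conventions", {
  g <- build_graph("CCCC")
  expect_equal(moran_autocorrelation(g, 10), 0)  # lag beyond diameter
  expect_equal(geary_autocorrelation(g, 10), 0)
  expect_equal(moran_autocorrelation(g, 1), 0)   # all weights equal
  expect_equal(geary_autocorrelation(g, 1), 0)
})

test_that("autocorrelations match a hand-evaluated weighted chain", {
  # 3-atom chain with weights (1, 2, 1), lag 2: single ordered pair (1,3)x2
  g <- fake_graph(rbind(c(1, 2), c(2, 3)), weights = c(1, 2, 1))
  w <- c(1, 2, 1); wb <- mean(w)
  num <- ((w[1] - wb) * (w[3] - wb) * 2) / 2
  den <- sum((w - wb)^2) / 3
  expect_equal(moran_autocorrelation(g, 2, scaled = FALSE), num / den)
  # lag 1: ordered pairs (1,2),(2,1),(2,3),(3,2)
  gnum <- (2 * (w[1] - w[2])^2 + 2 * (w[2] - w[3])^2) / (2 * 4)
  gden <- sum((w - wb)^2) / 2
  expect_equal(geary_autocorrelation(g, 1, scaled = FALSE), gnum / gden)
})

test_that("McGowan volume reproduces published increment sums", {
  # methane: (16.35 + 4*8.71 - 4*6.56) / 100
  expect_equal(mcgowan_volume(build_graph("C")), 0.2495)
  # ethane: 2 C + 6 H, 7 bonds
  expect_equal(mcgowan_volume(build_graph("CC")),
               (2 * 16.35 + 6 * 8.71 - 7 * 6.56) / 100)
  # one krypton-free degenerate case: single heavy atom, no bonds beyond H
  expect_equal(mcgowan_volume(build_graph("FF")),  # F2: 2 F, 1 bond
               (2 * 10.48 - 6.56) / 100)
})

test_that("surface area and packing density behave consistently", {
  sa_eth <- vsa_total(build_graph("CC"))
  sa_prop <- vsa_total(build_graph("CCC"))
  expect_gt(sa_eth, 0)
  expect_gt(sa_prop, sa_eth)   # monotone in added atoms of the same type
  g <- build_graph("C")
  expect_equal(packing_density_index(g), mcgowan_volume(g) / vsa_total(g))
  contrib <- vsa_total(build_graph("CCC"), per_atom = TRUE)
  expect_length(contrib, 3)
  expect_equal(sum(contrib), sa_prop)
})

test_that("descriptors agree with brute-force oracles on random graphs", {
  set.seed(91)
  for (rep in 1:60) {
    g <- random_connected_graph(10)
    ord <- sample(1:5, 1)
    expect_equal(avg_connectivity_index(g, ord),
                 oracle_avg_connectivity(g, ord), tolerance = 1e-12)
    expect_equal(eccentric_deviation(g), oracle_eccentric_deviation(g),
                 tolerance = 1e-12)
    lag <- sample(1:4, 1)
    w <- scaled_weights(g, "mass")
    expect_equal(moran_autocorrelation(g, lag, "mass"),
                 oracle_moran(g, lag, w), tolerance = 1e-10)
    wv <- scaled_weights(g, "vdw_volume")
    expect_equal(geary_autocorrelation(g, lag, "vdw_volume"),
                 oracle_geary(g, lag, wv), tolerance = 1e-10)
  }
})

test_that("edge-adjacency eigenvalues conserve the bond-order trace", {
  set.seed(17)
  for (rep in 1:20) {
    g <- random_connected_graph(9)
    nb <- nrow(g$bonds)
    eigs <- vapply(seq_len(nb), function(k) {
      augmented_edge_adjacency_eig(g, k)
    }, numeric(1))
    expect_equal(sum(eigs), sum(g$bonds$order), tolerance = 1e-8)
  }
  # with a double bond in the diagonal
  g2 <- build_graph("C=CC")
  expect_equal(augmented_edge_adjacency_eig(g2, 1) +
                 augmented_edge_adjacency_eig(g2, 2), 3, tolerance = 1e-10)
})

test_that("descriptors are invariant under atom reindexing", {
  pairs <- list(
    c("CCCCC", "C(CC)CC"),
    c("OC(=O)C(F)(F)F", "FC(F)(F)C(O)=O"),
    c("OS(=O)(=O)C(F)(F)C(F)(F)F", "C(F)(F)(S(O)(=O)=O)C(F)(F)F")
  )
  descs <- c("X4A", "DECC", "Eig12_AEA_bo", "PDI", "MATS8m", "GATS8v", "Vx",
             "SAtot")
  for (p in pairs) {
    t1 <- descriptor_table(p[1], names = descs)
    t2 <- descriptor_table(p[2], names = descs)
    expect_equal(as.numeric(t1[1, -1]), as.numeric(t2[1, -1]),
                 tolerance = 1e-10)
  }
})

test_that("descriptor tables are deterministic and row-stable", {
  smis <- c(a = "CCO", b = "OC(=O)C(F)(F)F", c = "CCO")
  tab <- descriptor_table(smis, names = c("X4A", "DECC", "PDI"))
  expect_equal(dim(tab), c(3, 4))
  expect_false(anyNA(tab[, -1]))
  # duplicate compounds give identical rows
  expect_equal(as.numeric(tab[1, -1]), as.numeric(tab[3, -1]))
  # permuting the input permutes the rows identically
  tab2 <- descriptor_table(smis[c(2, 1, 3)], names = c("X4A", "DECC", "PDI"))
  expect_equal(as.numeric(tab2[1, -1]), as.numeric(tab[2, -1]))
  # per-compound failure does not abort the batch
  tab3 <- descriptor_table(c(ok = "CC", bad = "C1CC"), names = c("X4A"))
  expect_false(is.na(tab3$X4A[1]))
  expect_true(is.na(tab3$X4A[2]))
  expect_named(attr(tab3, "errors"), "bad")
  expect_error(descriptor_table("CC", names = "NOPE"), "valid names")
})

test_that("the seven modeled descriptors compute for the whole study set", {
  ds <- pfas_hsa_data()
  tab <- descriptor_table(ds)
  expect_equal(dim(tab), c(24, 8))
  expect_false(anyNA(tab[, -1]))
  expect_true(all(tab$PDI > 0))
  expect_true(all(tab$QED > 0 & tab$QED <= 1))
})
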