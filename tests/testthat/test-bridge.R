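# Charged-pair distance engine and state-comparison aggregation.

# small hand-built model: ASP (OD1, OD2) + LYS (NZ) at chosen positions
asp_lys_model <- function(od1, od2, nz) {
  atoms <- data.frame(
    chain_id = "A", resid = c(10L, 10L, 10L, 20L, 20L), icode = "",
    resname = c("ASP", "ASP", "ASP", "LYS", "LYS"),
    atom_name = c("CA", "OD1", "OD2", "CA", "NZ"),
    element = c("C", "O", "O", "C", "N"), altloc = "", is_hetero = FALSE)
  xyz <- rbind(c(-2, 0, 0), od1, od2, c(10, 10, 10), nz)
  pdb_ensemble(atoms, array(xyz, c(5, 3, 1)))
}

test_that("distance is the minimum over terminal-atom cross pairs", {
  e <- asp_lys_model(od1 = c(0, 0, 0), od2 = c(4, 0, 0), nz = c(3, 0, 0))
  p <- pair_spec("dk", residue_ref("A", 10, resname = "ASP"),
                 residue_ref("A", 20, resname = "LYS"))
  # min over {d(OD1,NZ)=3, d(OD2,NZ)=1} = 1
  expect_equal(charged_pair_distance(e, p), 1.0)
})

test_that("single-atom residues give the plain Euclidean distance", {
  atoms <- data.frame(
    chain_id = "A", resid = c(10L, 20L), icode = "",
    resname = c("GLU", "ARG"), atom_name = c("OE1", "NH1"),
    element = c("O", "N"), altloc = "", is_hetero = FALSE)
  e <- pdb_ensemble(atoms, array(rbind(c(0, 0, 0), c(0, 3, 4)), c(2, 3, 1)))
  p <- pair_spec("er", residue_ref("A", 10, resname = "GLU"),
                 residue_ref("A", 20, resname = "ARG"))
  expect_equal(suppressWarnings(charged_pair_distance(e, p)), 5.0)
})

test_that("random geometries agree with the exhaustive brute-force oracle", {
  for (s in 1:60) {
    g <- random_pair_ensemble(s)
    expect_equal(suppressWarnings(charged_pair_distance(g$ensemble, g$spec)),
                 oracle_pair_distance(g$ensemble, g$ref_a, g$ref_b),
                 tolerance = 1e-12)
  }
})

test_that("distance is symmetric and rigid-motion invariant", {
  for (s in 1:10) {
    g <- random_pair_ensemble(s)
    d_ab <- suppressWarnings(charged_pair_distance(g$ensemble, g$spec))
    rev_spec <- pair_spec("rev", g$spec$b, g$spec$a)
    expect_equal(suppressWarnings(charged_pair_distance(g$ensemble, rev_spec)),
                 d_ab)
    moved <- apply_rigid(g$ensemble, angle = 0.3 + s / 10,
                         axis = c(s, 1, 2), shift = c(5, -2, 1))
    expect_equal(suppressWarnings(charged_pair_distance(moved, g$spec)), d_ab,
                 tolerance = 1e-9)
  }
})

test_that("a non acid/base pair warns and falls back to the generic rule", {
  atoms <- data.frame(
    chain_id = "A", resid = c(10L, 20L), icode = "",
    resname = c("LYS", "ARG"), atom_name = c("NZ", "NH1"),
    element = "N", altloc = "", is_hetero = FALSE)
  e <- pdb_ensemble(atoms, array(rbind(c(0, 0, 0), c(2, 0, 0)), c(2, 3, 1)))
  p <- pair_spec("kk", residue_ref("A", 10, resname = "LYS"),
                 residue_ref("A", 20, resname = "ARG"))
  ws <- capture_warnings(d <- charged_pair_distance(e, p))
  expect_match(ws, "generic", all = FALSE)   # plus a missing-atom warning
  expect_equal(d, 2.0)
})

test_that("min_over_chain_pairs never exceeds the intra distance", {
  # same pair duplicated in chains A and B, chain B copy much closer
  mk <- function(chain, gap) {
    atoms <- data.frame(
      chain_id = chain, resid = c(10L, 20L), icode = "",
      resname = c("GLU", "LYS"), atom_name = c("OE1", "NZ"),
      element = c("O", "N"), altloc = "", is_hetero = FALSE)
    list(atoms = atoms, xyz = rbind(c(0, 0, 0), c(gap, 0, 0)))
  }
  a <- mk("A", 8); b <- mk("B", 8)
  b$xyz <- b$xyz + 3  # chain B offset; cross-chain A-B gap is smaller
  e <- pdb_ensemble(rbind(a$atoms, b$atoms),
                    array(rbind(a$xyz, b$xyz), c(4, 3, 1)))
  intra <- pair_spec("i", residue_ref("A", 10, resname = "GLU"),
                     residue_ref("A", 20, resname = "LYS"))
  global <- pair_spec("g", residue_ref("A", 10, resname = "GLU"),
                      residue_ref("A", 20, resname = "LYS"),
                      chain_mode = "min_over_chain_pairs")
  d_intra <- suppressWarnings(charged_pair_distance(e, intra))
  d_min <- suppressWarnings(charged_pair_distance(e, global))
  expect_lte(d_min, d_intra)
  expect_equal(d_intra, 8)
  expect_equal(d_min, sqrt(43))  # OE1(B) at (3,3,3) to NZ(A) at (8,0,0)
})

test_that("ensemble statistics match a naive per-model loop", {
  p <- default_bridge_pair()
  e <- gen_bridge_ensemble(list(list(spec = p, mean_A = 8, sd_A = 0.5)),
                           n_models = 20, seed = 42)
  st <- ensemble_distance_stats(e, p)
  d <- numeric(0)
  for (m in 1:20) d <- c(d, charged_pair_distance(e, p, m))
  expect_equal(st$mean_A, sum(d) / 20)
  expect_equal(st$sd_A, sqrt(sum((d - mean(d))^2) / 19))
  expect_equal(st$n, 20L)
  # single-model ensemble: sd 0, n 1
  e1 <- gen_bridge_ensemble(list(list(spec = p, mean_A = 3.2, sd_A = 0)),
                            n_models = 1, seed = 1)
  st1 <- ensemble_distance_stats(e1, p)
  expect_equal(st1$mean_A, 3.2, tolerance = 1e-9)
  expect_identical(st1$sd_A, 0)
})

test_that("pooled mean equals the n-weighted mean of per-ensemble means", {
  p <- default_bridge_pair()
  e1 <- gen_bridge_ensemble(list(list(spec = p, mean_A = 8, sd_A = 0.5)),
                            n_models = 5, seed = 1)
  e2 <- gen_bridge_ensemble(list(list(spec = p, mean_A = 8, sd_A = 0.5)),
                            n_models = 12, seed = 2)
  tab <- state_comparison_table(list(cond = list(e1, e2)), list(p))
  s1 <- ensemble_distance_stats(e1, p)
  s2 <- ensemble_distance_stats(e2, p)
  expect_equal(tab$long$mean_A,
               (s1$mean_A * s1$n + s2$mean_A * s2$n) / (s1$n + s2$n))
  expect_equal(tab$long$n, 17L)
})

test_that("degenerate table equals single-ensemble statistics", {
  p <- default_bridge_pair()
  e <- gen_bridge_ensemble(list(list(spec = p, mean_A = 6, sd_A = 0.2)),
                           n_models = 1, seed = 3, source_label = "apo")
  tab <- state_comparison_table(list(apo = e), list(p))
  st <- ensemble_distance_stats(e, p, condition = "apo")
  expect_equal(tab$long, st)
})

test_that("delta tables are antisymmetric in their condition arguments", {
  sc_pairs <- canonical_pairs()
  means_a <- c(hlh_tdh = 12, hlh_tdhN = 11, ard6_hlh = 15, s2s3_tdh = 6)
  means_b <- c(hlh_tdh = 4, hlh_tdhN = 4.5, ard6_hlh = 15, s2s3_tdh = 10)
  mk <- function(means, seed, lab)
    gen_bridge_ensemble(lapply(names(means), function(k)
      list(spec = sc_pairs[[k]], mean_A = unname(means[k]), sd_A = 0.3)),
      n_models = 4, seed = seed, source_label = lab)
  tab <- state_comparison_table(
    list(apo = mk(means_a, 1, "apo"), bound = mk(means_b, 2, "bound")),
    unname(sc_pairs))
  fwd <- delta_table(tab, "apo", "bound")
  rev <- delta_table(tab, "bound", "apo")
  expect_equal(fwd$delta_mean_A, -rev$delta_mean_A)
  expect_equal(nrow(tab$long), 8L)
})

test_that("contact classification is boundary-inclusive at the cutoff", {
  expect_identical(classify_contact(c(3.9, 4.0, 4.01)),
                   c("formed", "formed", "broken"))
  expect_error(classify_contact(-1))
})
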