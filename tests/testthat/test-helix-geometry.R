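test_that("backbone hydrogens sit 1.0 A from N, none at chain starts or prolines", {
  s <- make_ideal_helix(helix_spec("alpha", 10))
  pro <- as.data.frame(s)
  pro$resid[pro$resno == 5] <- "PRO"
  sh <- place_backbone_hydrogens(nr_structure(pro))
  h <- as.data.frame(sh[sh$elety == "H", ])
  expect_setequal(h$resno, setdiff(2:10, 5))       # no H at residue 1 or the proline
  for (i in h$resno) {
    hv <- unlist(h[h$resno == i, c("x", "y", "z")])
    nv <- unlist(sh[sh$resno == i & sh$elety == "N", c("x", "y", "z")])
    expect_equal(sqrt(sum((hv - nv)^2)), 1.0, tolerance = 1e-9)
  }
})

test_that("Kabsch-Sander bonds reproduce the canonical helix offsets", {
  sa <- place_backbone_hydrogens(make_ideal_helix(helix_spec("alpha", 20)))
  hba <- compute_hbonds_ks(sa)
  expect_true(all(hba$offset == 4))
  expect_true(all(hba$energy < -0.5))
  # every interior donor is bonded
  expect_true(all(6:19 %in% hba$donor))

  sp <- place_backbone_hydrogens(make_ideal_helix(helix_spec(c("alpha", "pi", "alpha"), c(8, 6, 8))))
  hbp <- compute_hbonds_ks(sp)
  expect_true(any(hbp$offset == 5))

  # two residues far apart: no bonds
  s <- make_ideal_helix(helix_spec("alpha", 6))
  iso <- as.data.frame(s)
  iso$x[iso$resno > 3] <- iso$x[iso$resno > 3] + 50
  expect_equal(nrow(compute_hbonds_ks(place_backbone_hydrogens(nr_structure(iso)))), 0)
})

test_that("Kabsch-Sander energies are rigid-motion invariant", {
  s <- place_backbone_hydrogens(make_ideal_helix(helix_spec(c("alpha", "pi", "alpha"), c(7, 5, 7))))
  hb1 <- compute_hbonds_ks(s)
  s2 <- nrpiturn:::transform_structure(s, nrpiturn:::rigid_motion())
  hb2 <- compute_hbonds_ks(s2)
  expect_identical(hb1$donor, hb2$donor)
  expect_identical(hb1$acceptor, hb2$acceptor)
  expect_lt(max(abs(hb1$energy - hb2$energy)), 1e-9)
})

test_that("every residue gets exactly one class and runs tile the chain", {
  set.seed(31)
  for (rep in 1:10) {
    lens <- sample(5:9, 3, replace = TRUE)
    cls <- sample(c("alpha", "pi", "three_ten"), 3, replace = TRUE)
    s <- make_ideal_helix(helix_spec(cls, lens))
    sh <- place_backbone_hydrogens(s)
    a <- assign_helix_types(sh, compute_hbonds_ks(sh))
    expect_equal(nrow(a), sum(lens))
    expect_true(all(a$class %in% c("alpha", "pi", "three_ten", "turn", "coil")))
    expect_identical(a$resno, seq_len(sum(lens)))
  }
})

test_that("ideal helices of each class are classified as that class", {
  sh <- place_backbone_hydrogens(make_ideal_helix(helix_spec("three_ten", 12)))
  a <- assign_helix_types(sh, compute_hbonds_ks(sh))
  expect_true(all(a$class[3:9] == "three_ten"))

  sc <- place_backbone_hydrogens(make_ideal_helix(helix_spec("coil", 10)))
  ac <- assign_helix_types(sc, compute_hbonds_ks(sc))
  expect_true(all(!ac$class %in% c("alpha", "pi", "three_ten")))
})

test_that("pi spans are detected with bulge and flanking annotation", {
  s <- make_ideal_helix(helix_spec(c("alpha", "pi", "alpha"), c(8, 6, 8)))
  sh <- place_backbone_hydrogens(s)
  a <- assign_helix_types(sh, compute_hbonds_ks(sh))
  spans <- detect_pi_turns(a, sh)
  core <- spans[!spans$weak, ]
  expect_equal(nrow(core), 1)
  expect_true(core$flanked)
  expect_gte(core$bulge_resno, core$first_resno)
  expect_lte(core$bulge_resno, core$last_resno)
  expect_gt(core$bulge_dist, 1.0)          # the bulge protrudes off-axis

  sa <- place_backbone_hydrogens(make_ideal_helix(helix_spec("alpha", 20)))
  aa <- assign_helix_types(sa, compute_hbonds_ks(sa))
  expect_equal(nrow(detect_pi_turns(aa, sa)), 0)

  # pi stretch at the terminus is reported unflanked
  st <- place_backbone_hydrogens(make_ideal_helix(helix_spec(c("pi", "alpha"), c(7, 10))))
  at <- assign_helix_types(st, compute_hbonds_ks(st))
  sp <- detect_pi_turns(at, st)
  expect_false(sp$flanked[1])
})

test_that("salt bridge deduplication keeps one record per residue pair", {
  atoms <- data.frame(
    chain = "A", resno = c(1, 1, 1, 2, 2), ins = "",
    resid = c("ARG", "ARG", "ARG", "GLU", "GLU"),
    elety = c("NH1", "NH2", "NE", "OE1", "OE2"),
    elesy = c("N", "N", "N", "O", "O"),
    x = c(0, 0.5, 1, 3.0, 3.2), y = 0, z = 0, stringsAsFactors = FALSE)
  sb <- detect_salt_bridges(nr_structure(atoms))
  expect_equal(nrow(sb), 1)                        # several close atom pairs, one record
  expect_equal(sb$distance, 2.0, tolerance = 1e-9) # the minimal pair distance
})

test_that("motif conformation verdicts separate pi-turn from plain alpha motifs", {
  # pi-turn + bridged R/E at canonical spacing -> pi-turn-motif
  s <- make_ideal_helix(helix_spec(c("alpha", "pi", "alpha"), c(8, 6, 8)))
  df <- as.data.frame(s)
  df$resid[df$resno == 10] <- "ARG"; df$resid[df$resno == 14] <- "GLU"
  ca10 <- unlist(df[df$resno == 10 & df$elety == "CA", c("x", "y", "z")])
  ca14 <- unlist(df[df$resno == 14 & df$elety == "CA", c("x", "y", "z")])
  mid <- (ca10 + ca14) / 2; u <- (ca14 - ca10) / sqrt(sum((ca14 - ca10)^2))
  df <- rbind(df, data.frame(chain = "A", resno = c(10, 14), ins = "",
                             resid = c("ARG", "GLU"), elety = c("NH1", "OE1"),
                             elesy = c("N", "O"),
                             x = c(mid[1] - 1.4 * u[1], mid[1] + 1.4 * u[1]),
                             y = c(mid[2] - 1.4 * u[2], mid[2] + 1.4 * u[2]),
                             z = c(mid[3] - 1.4 * u[3], mid[3] + 1.4 * u[3])))
  df <- df[order(df$resno), ]
  v <- verify_motif_conformation(nr_structure(df), "A", 10, 14)
  expect_equal(v$verdict, "pi-turn-motif")
  expect_true(v$intra_helical_salt_bridge)

  # straight alpha helix, same spacing, no bridge atoms -> motif-without-pi-turn
  s2 <- make_ideal_helix(helix_spec("alpha", 20))
  df2 <- as.data.frame(s2)
  df2$resid[df2$resno == 8] <- "ARG"; df2$resid[df2$resno == 12] <- "GLU"
  v2 <- verify_motif_conformation(nr_structure(df2), "A", 8, 12)
  expect_equal(v2$verdict, "motif-without-pi-turn")
  expect_false(v2$pi_turn_present)

  # wrong spacing -> no motif; missing residue -> error
  v3 <- verify_motif_conformation(nr_structure(df2), "A", 8, 14)
  expect_equal(v3$verdict, "no-motif")
  expect_error(verify_motif_conformation(nr_structure(df2), "A", 8, 99), "not found")

  # 3-10 junction flag responds to the supplied window
  s4 <- make_ideal_helix(helix_spec(c("alpha", "three_ten"), c(12, 6)))
  df4 <- as.data.frame(s4)
  df4$resid[df4$resno == 3] <- "ARG"; df4$resid[df4$resno == 7] <- "GLU"
  v4 <- verify_motif_conformation(nr_structure(df4), "A", 3, 7,
                                  junction_window = c(13, 18))
  expect_true(v4$three_ten_junction_present)
})

test_that("inter-chain salt bridge detection is symmetric in chain order", {
  s <- make_toy_dimer(12, 16, data.frame(resA = 6, resB = 7, dist = 3.0))
  sb <- detect_salt_bridges(s, scope = "inter")
  expect_equal(nrow(sb), 1)
  # swap the chain labels; same bridge, same distance
  sw <- as.data.frame(s); sw$chain <- ifelse(sw$chain == "A", "B", "A")
  sw <- sw[order(sw$chain, sw$resno), ]
  sb2 <- detect_salt_bridges(nr_structure(sw), scope = "inter")
  expect_equal(nrow(sb2), 1)
  expect_equal(sb$distance, sb2$distance, tolerance = 1e-9)
})

test_that("pi-span calls agree with an independent DSSP implementation", {
  s <- make_ideal_helix(helix_spec(c("alpha", "pi", "alpha"), c(8, 6, 8)))
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import mdtraj as md; t = md.load('", f, "'); ",
    "print(''.join(md.compute_dssp(t, simplified=False)[0]))"))),
    stdout = TRUE)
  dssp <- strsplit(out[length(out)], "")[[1]]
  ref_span <- range(which(dssp == "I"))
  sh <- place_backbone_hydrogens(s)
  a <- assign_helix_types(sh, compute_hbonds_ks(sh))
  ours <- class_spans(a$class, "pi")
  expect_equal(nrow(ours), 1)
  expect_lte(abs(ours[1, "start"] - ref_span[1]), 1)
  expect_lte(abs(ours[1, "end"] - ref_span[2]), 1)
})
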