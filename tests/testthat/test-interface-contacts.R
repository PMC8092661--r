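# Element ranges for a 30-residue toy helix pair: the N-terminal stretch
# plays helix H7, the middle stretch the loop H8-H9.
toy_em <- function(n = 30) {
  rng <- list(H7 = c(1, 13), `loopH8-H9` = c(14, 26), H10 = c(27, n))
  element_map(list(A = rng, B = rng))
}

test_that("contact enumeration types and deduplicates correctly", {
  s <- make_toy_dimer(24, 16, data.frame(resA = 6, resB = 6, dist = 2.8))
  cc <- enumerate_interface_contacts(s, "A", "B")
  expect_equal(nrow(cc), 1)
  expect_equal(cc$type, "salt_bridge")     # salt_bridge wins over hbond typing

  far <- make_toy_dimer(10, 30)
  expect_equal(nrow(enumerate_interface_contacts(far, "A", "B")), 0)
  expect_error(enumerate_interface_contacts(far, "A", "C"), "chain absent")

  # a VdW-range bridge types as vdw, not salt_bridge or hbond
  sv <- make_toy_dimer(24, 16, data.frame(resA = 6, resB = 6, dist = 4.4))
  cv <- enumerate_interface_contacts(sv, "A", "B")
  expect_equal(cv$type, "vdw")
})

test_that("a single bridging water yields one water_mediated record", {
  s <- make_toy_dimer(10, 14)
  nA <- unlist(s[s$chain == "A" & s$resno == 5 & s$elety == "N", c("x", "y", "z")])
  nB <- unlist(s[s$chain == "B" & s$resno == 5 & s$elety == "N", c("x", "y", "z")])
  w <- (nA + nB) / 2
  d <- rbind(as.data.frame(s),
             data.frame(chain = "W", resno = 999, ins = "", resid = "HOH",
                        elety = "O", elesy = "O", x = w[1], y = w[2], z = w[3]))
  dist_w <- sqrt(sum((w - nA)^2))
  sw <- nr_structure(d)
  cc <- enumerate_interface_contacts(sw, "A", "B",
                                     cutoffs = within(default_contact_cutoffs(),
                                                      water <- dist_w + 0.1))
  wm <- cc[cc$type == "water_mediated", ]
  expect_gte(nrow(wm), 1)
  expect_true(all(wm$water == 999))
  # with a cutoff below every water-polar distance the record disappears
  cc2 <- enumerate_interface_contacts(sw, "A", "B",
                                      cutoffs = within(default_contact_cutoffs(),
                                                       water <- 3.0))
  expect_equal(sum(cc2$type == "water_mediated"), 0)
})

test_that("element binning is total and routes unknown residues to other", {
  s <- make_toy_dimer(30, 16, data.frame(resA = c(2, 8), resB = c(15, 21),
                                         dist = c(3.0, 3.0)))
  cc <- enumerate_interface_contacts(s, "A", "B")
  m <- bin_contacts_by_element(cc, toy_em())
  expect_equal(m$total, nrow(cc))
  expect_equal(sum(m$counts$n[m$counts$elementA == "H7" &
                              m$counts$elementB == "loopH8-H9"]), 2)

  m0 <- bin_contacts_by_element(cc[0, ], toy_em())
  expect_equal(m0$total, 0)

  em_partial <- element_map(list(A = list(H7 = c(1, 1)), B = list(H7 = c(1, 1))))
  mo <- bin_contacts_by_element(cc, em_partial)
  expect_true(all(mo$counts$elementA == "other"))

  expect_error(element_map(list(A = list(H7 = c(1, 5), H8 = c(4, 9)))), "overlap")
})

test_that("asymmetry score is signed and zero for symmetric interfaces", {
  # three H7_A -> loopH8-H9_B bridges, none in the reverse orientation
  s <- make_toy_dimer(30, 16, data.frame(resA = c(1, 7, 13), resB = c(14, 20, 26),
                                         dist = c(3.0, 3.0, 3.0)))
  m <- bin_contacts_by_element(enumerate_interface_contacts(s, "A", "B"), toy_em())
  mr <- bin_contacts_by_element(enumerate_interface_contacts(s, "B", "A"), toy_em())
  expect_equal(asymmetry_score(m, mr), 3)
  expect_equal(asymmetry_score(mr, m), -3)

  # mirror-designed homodimer: H7-H7 and loop-loop contacts only -> 0
  s2 <- make_toy_dimer(30, 16, data.frame(resA = c(2, 20), resB = c(2, 20),
                                          dist = c(3.0, 3.0)))
  m2 <- bin_contacts_by_element(enumerate_interface_contacts(s2, "A", "B"), toy_em())
  m2r <- bin_contacts_by_element(enumerate_interface_contacts(s2, "B", "A"), toy_em())
  expect_equal(asymmetry_score(m2, m2r), 0)
})

test_that("contact enumeration is symmetric under chain-label swap", {
  s <- make_toy_dimer(24, 16, data.frame(resA = c(2, 9), resB = c(4, 11),
                                         dist = c(3.0, 4.2)))
  ab <- enumerate_interface_contacts(s, "A", "B")
  ba <- enumerate_interface_contacts(s, "B", "A")
  expect_equal(nrow(ab), nrow(ba))
  ka <- sort(paste(ab$resnoA, ab$resnoB, ab$type, round(ab$distance, 6)))
  kb <- sort(paste(ba$resnoB, ba$resnoA, ba$type, round(ba$distance, 6)))
  expect_identical(ka, kb)
})

test_that("binned totals equal contact counts on fuzz dimers", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(15:24, 1)
    nb <- sample(0:3, 1)
    pos <- seq(2, n - 1, by = 5)[seq_len(min(nb, length(seq(2, n - 1, by = 5))))]
    bp <- if (length(pos)) data.frame(resA = pos, resB = pos,
                                      dist = runif(length(pos), 2.8, 4.4)) else NULL
    s <- make_toy_dimer(n, 16, bp)
    cc <- enumerate_interface_contacts(s, "A", "B")
    m <- bin_contacts_by_element(cc, toy_em(n))
    expect_equal(m$total, nrow(cc))
    expect_equal(nrow(cc), length(pos))
  }
})

test_that("isolated-sphere SASA matches the closed form within 2 percent", {
  one <- nr_structure(data.frame(chain = "A", resno = 1, ins = "", resid = "GLY",
                                 elety = "O", elesy = "O", x = 0, y = 0, z = 0))
  a <- compute_sasa(one)
  expect_lt(abs(a - 4 * pi * (1.52 + 1.4)^2) / (4 * pi * (1.52 + 1.4)^2), 0.02)

  two <- nr_structure(data.frame(chain = "A", resno = 1:2, ins = "", resid = "GLY",
                                 elety = "O", elesy = "O",
                                 x = c(0, 30), y = 0, z = 0))
  a2 <- compute_sasa(two)
  expect_equal(unname(a2[1]), unname(a2[2]), tolerance = 1e-9)
  expect_equal(unname(a2[1]), unname(a[1]), tolerance = 1e-9)
})

test_that("a caged atom loses nearly all accessible surface", {
  # 12 neighbours at contact distance (icosahedral shell) bury the centre
  phi <- (1 + sqrt(5)) / 2
  shell <- rbind(
    as.matrix(expand.grid(x = c(-1, 1), y = c(-phi, phi), z = 0)),
    as.matrix(expand.grid(x = 0, y = c(-1, 1), z = c(-phi, phi))),
    as.matrix(expand.grid(x = c(-phi, phi), y = 0, z = c(-1, 1))))
  shell <- shell / sqrt(1 + phi^2) * 2.6
  at <- data.frame(chain = "A", resno = seq_len(13), ins = "", resid = "GLY",
                   elety = "C", elesy = "C",
                   x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]))
  a <- compute_sasa(nr_structure(at))
  iso <- 4 * pi * (1.70 + 1.4)^2
  expect_lt(a[[1]], 0.05 * iso)
})

test_that("buried surface area is symmetric, rigid-motion invariant, near zero when apart", {
  far <- make_toy_dimer(8, 30)
  expect_lt(abs(buried_surface_area(far, "A", "B")), 1)

  s <- make_toy_dimer(8, 16, data.frame(resA = 4, resB = 4, dist = 3.0))
  b1 <- buried_surface_area(s, "A", "B")
  expect_gt(b1, 0)
  expect_equal(buried_surface_area(s, "B", "A"), b1, tolerance = 1e-6)
  s2 <- nrpiturn:::transform_structure(s, nrpiturn:::rigid_motion())
  expect_lt(abs(buried_surface_area(s2, "A", "B") - b1), 2)
  expect_error(buried_surface_area(s, "A", "Z"), "chain absent")
})
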