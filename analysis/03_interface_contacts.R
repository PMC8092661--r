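#!/usr/bin/env Rscript
# Dimer-interface analysis on designed toy dimers: an asymmetric interface
# (helix H7 of chain A against the loop H8-H9 of chain B, the RXR-like
# orientation) versus a mirror-symmetric homodimer, with contact typing,
# element binning, the signed asymmetry score and buried surface area.
suppressMessages(library(nrpiturn))
dir.create("results", showWarnings = FALSE)

em <- element_map(list(
  A = list(H7 = c(1, 13), `loopH8-H9` = c(14, 26), H10 = c(27, 30)),
  B = list(H7 = c(1, 13), `loopH8-H9` = c(14, 26), H10 = c(27, 30))))

asym <- make_toy_dimer(30, 16, data.frame(resA = c(1, 7, 13), resB = c(14, 20, 26),
                                          dist = c(2.8, 3.0, 3.2)))
cc <- enumerate_interface_contacts(asym, "A", "B")
write.table(cc, "results/interface_contacts.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
m <- bin_contacts_by_element(cc, em)
mr <- bin_contacts_by_element(enumerate_interface_contacts(asym, "B", "A"), em)
score <- asymmetry_score(m, mr)

sym <- make_toy_dimer(30, 16, data.frame(resA = c(2, 20), resB = c(2, 20),
                                         dist = c(3.0, 3.0)))
ms <- bin_contacts_by_element(enumerate_interface_contacts(sym, "A", "B"), em)
msr <- bin_contacts_by_element(enumerate_interface_contacts(sym, "B", "A"), em)
score_sym <- asymmetry_score(ms, msr)

bsa_asym <- buried_surface_area(asym, "A", "B")
bsa_far <- buried_surface_area(make_toy_dimer(30, 40), "A", "B")

jsonlite::write_json(list(
  asymmetric = list(contacts = nrow(cc), score = score, bsa = bsa_asym),
  symmetric = list(score = score_sym),
  separated = list(bsa = bsa_far)),
  "results/interface_summary.json", auto_unbox = TRUE, digits = NA)

cat("Asymmetric dimer:", nrow(cc), "interface contacts (",
    paste(names(table(cc$type)), table(cc$type), collapse = ", "), ")\n")
cat("Asymmetry score (H7_A x loopH8-H9_B minus the reverse):", score,
    "- positive, chain A is the RXR-like side\n")
cat("Mirror-symmetric homodimer score:", score_sym, "\n")
cat(sprintf("Buried surface area: %.1f A^2 (contact dimer) vs %.2f A^2 (40 A apart)\n",
            bsa_asym, bsa_far))
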