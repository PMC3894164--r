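test_that("coarse-graining counts beads and bonded terms along a chain", {
  st <- helix_structure(10)
  top <- coarse_grain(st)
  expect_equal(nrow(top$beads), 10)
  expect_equal(nrow(top$bonds), 9)
  expect_equal(nrow(top$angles), 8)
  expect_equal(nrow(top$dihedrals), 7)   # helical: none degenerate
  expect_true(all(top$beads$radius == 5.3))
  # bead positions are exactly the C-alpha coordinates
  ca <- st$atoms[st$atoms$elety == "CA", ]
  expect_identical(top$coords[, 1], ca$x)
  expect_identical(top$coords[, 2], ca$y)
})

test_that("no bond crosses a chain break", {
  st1 <- helix_structure(4, chain = "A")
  st2 <- helix_structure(4, chain = "B")
  st2$atoms$x <- st2$atoms$x + 40
  st2$atoms$eleno <- st2$atoms$eleno + max(st1$atoms$eleno)
  atoms <- rbind(st1$atoms, st2$atoms)
  st <- annotate_structure(atoms, data.frame(chain = c("A", "B"), first = 1,
                                             last = 4, label = "structured"))
  top <- coarse_grain(st)
  expect_equal(nrow(top$bonds), 6)  # 3 per chain
  ch <- top$beads$chain
  expect_true(all(ch[top$bonds$i] == ch[top$bonds$j]))
})

test_that("a nucleotide complex maps to nine fully interconnected beads", {
  # synthetic complex: the seven named heavy atoms plus two Mg ions
  nuc_names <- c("C2", "C6", "N9", "C4'", "P1", "P2", "P3")
  xyz <- matrix(c(0, 0, 0,  1.4, 0, 0,  0.7, 1.2, 0,  2.5, 1.5, 0.5,
                  4, 2, 0,  5.5, 2.5, 0.3,  7, 3, 0.6,
                  6, 1, 1,  7.5, 1.5, 1.2), ncol = 3, byrow = TRUE)
  atoms <- data.frame(eleno = 1:9, elety = c(nuc_names, "MG", "MG"),
                      resid = c(rep("ANP", 7), "MG", "MG"), chain = "A",
                      resno = c(rep(101L, 7), 102L, 103L),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  st <- annotate_structure(atoms, data.frame(chain = "A", first = 101,
                                             last = 103,
                                             label = "nucleotide-complex"))
  top <- coarse_grain(st)
  expect_equal(nrow(top$beads), 9)
  expect_equal(nrow(top$bonds), choose(9, 2))
  expect_true(all(top$beads$radius == 3.5))
  expect_true(all(top$beads$kind == "nucleotide"))
  # phosphates -4/3 each, Mg +2 each: the complex is net neutral
  top <- assign_charges(top)
  expect_equal(total_charge(top), 0, tolerance = 1e-12)
  expect_equal(top$beads$charge[top$beads$resname == "P1"], -4 / 3)
  expect_equal(top$beads$charge[top$beads$resname == "MG"], c(2, 2))
})

test_that("missing C-alpha or nucleotide atoms raise named errors", {
  st <- helix_structure(3)
  st$atoms <- st$atoms[!(st$atoms$resno == 2 & st$atoms$elety == "CA"), ]
  expect_error(coarse_grain(st), "A:2")
})

test_that("native-contact detection matches the brute-force all-atom oracle", {
  st <- helix_structure(8)
  top <- coarse_grain(st)
  con <- detect_native_contacts(st, top)
  oracle <- contacts_oracle(st, top)
  got <- con[order(con$i, con$j), c("i", "j")]
  want <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  expect_equal(unname(as.matrix(got)), unname(want))
  # sigma is the pseudo-atom (C-alpha) separation
  for (r in seq_len(nrow(con)))
    expect_equal(con$sigma[r],
                 sqrt(sum((top$coords[con$i[r], ] - top$coords[con$j[r], ])^2)))
  expect_true(all(con$eps == 0.6))
})

test_that("the 5.5 A cutoff and the 3-residue separation rule are exact", {
  # two 1-atom residues at a controlled distance, far along the sequence
  mk <- function(gap) {
    atoms <- data.frame(eleno = 1:6, elety = "CA", resid = "ALA", chain = "A",
                        resno = 1:6,
                        x = c(0, 3.8, 7.6, 11.4, 15.2, 15.2 + gap),
                        y = c(0, 0, 0, 0, 0, 0) + c(0, 0, 0, 0, 0, 0),
                        z = 0, stringsAsFactors = FALSE)
    # put residue 6 next to residue 1 spatially
    atoms$x[6] <- gap; atoms$y[6] <- 0.0
    annotate_structure(atoms, data.frame(chain = "A", first = 1, last = 6,
                                         label = "structured"))
  }
  near <- mk(5.4); far <- mk(5.6)
  cn <- detect_native_contacts(near)
  cf <- detect_native_contacts(far)
  expect_true(any(cn$i == 1 & cn$j == 6))
  expect_false(any(cf$i == 1 & cf$j == 6))
  # i, i+2 at 4 A: excluded by the separation rule
  atoms <- data.frame(eleno = 1:3, elety = "CA", resid = "ALA", chain = "A",
                      resno = 1:3, x = c(0, 2, 4), y = c(0, 3.4, 0), z = 0,
                      stringsAsFactors = FALSE)
  st <- annotate_structure(atoms, data.frame(chain = "A", first = 1, last = 3,
                                             label = "structured"))
  expect_equal(nrow(detect_native_contacts(st)), 0)
})

test_that("only eligible regions form native contacts", {
  st <- helix_structure(8)
  st$regions$region[st$regions$resno > 4] <- "modeled"
  con <- detect_native_contacts(st, coarse_grain(st))
  expect_true(all(con$i <= 4 & con$j <= 4))
})

test_that("charge assignment follows the pH-7.6 rules", {
  seqres <- c("D", "A", "D", "E", "Y", "L", "I", "P", "Q")
  xyz <- cbind(3.8 * seq_along(seqres), 0, 0)
  top <- mk_chain_top(xyz, mk_beads(9, resname = "G"))
  top$beads$resname <- seqres
  top <- assign_charges(top, charge_termini = FALSE)
  expect_equal(top$beads$charge, c(-1, 0, -1, -1, 0, 0, 0, 0, 0))
  # histidine: fractional charge 10^(6-7.6)/(1+10^(6-7.6)) ~ 0.024 < 0.1 -> 0
  frac <- 10^(6 - 7.6) / (1 + 10^(6 - 7.6))
  toph <- mk_chain_top(xyz, mk_beads(9, resname = "G"))
  toph$beads$resname <- rep("HIS", 9)
  expect_equal(assign_charges(toph, charge_termini = FALSE)$beads$charge,
               rep(0, 9))
  expect_equal(
    assign_charges(toph, charge_termini = FALSE,
                   his_fractional = TRUE)$beads$charge,
    rep(frac, 9))
  # free termini carry +1 / -1
  topt <- assign_charges(mk_chain_top(xyz, mk_beads(9, resname = "A")))
  expect_equal(topt$beads$charge[1], 1)
  expect_equal(topt$beads$charge[9], -1)
  # unknown residue name: zero with a warning
  topu <- mk_chain_top(xyz, mk_beads(9, resname = "XXX"))
  expect_warning(topu <- assign_charges(topu, charge_termini = FALSE),
                 "unknown residue")
  expect_true(all(topu$beads$charge == 0))
})

test_that("P-site groups mirror one contact template onto both active sites", {
  # two chains; the P-site window lives in A's tail, the active site in both
  xyzA <- cbind(3.8 * (1:20), 0, 0)
  xyzB <- cbind(3.8 * (1:20), 15, 0)
  beads <- rbind(mk_beads(20, "A", resname = "A"),
                 mk_beads(20, "B", resname = "A"))
  top <- mk_chain_top(rbind(xyzA, xyzB), beads)
  top$bonds <- rbind(
    data.frame(i = 1:19, j = 2:20, r_eq = 3.8),
    data.frame(i = 21:39, j = 22:40, r_eq = 3.8))
  def <- list(site = "15A", chain = "A", resno = 15,
              contacts = data.frame(offset = rep(0, 9),
                                    partner_resno = 1:9,
                                    sigma = seq(5.5, 7.9, length.out = 9)))
  top2 <- build_psite_groups(top, list(def), receiver_chain = "A",
                             activator_chain = "B")
  expect_equal(length(top2$psite_groups), 2)
  prod <- top2$psite_groups[[1]]; mirr <- top2$psite_groups[[2]]
  expect_equal(prod$trigger, 9)
  expect_identical(prod$pairs$sigma, mirr$pairs$sigma)
  expect_false(any(prod$pairs$j == mirr$pairs$j))
  expect_true(prod$cis)
  # stripping removes every psite-tagged attractive term
  stripped <- strip_psite_attractions(top2)
  expect_false(any(grepl("^psite:", gophos:::active_contacts(stripped)$tag)))
  restored <- restore_psite_attractions(stripped)
  expect_identical(gophos:::active_contacts(restored),
                   gophos:::active_contacts(top2))
  # trigger-size validation
  def8 <- def; def8$contacts <- def$contacts[1:8, ]
  expect_error(build_psite_groups(top, list(def8), "A", "B"),
               "trigger size")
  expect_silent(build_psite_groups(top, list(def8), "A", "B",
                                   validate = FALSE))
})
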