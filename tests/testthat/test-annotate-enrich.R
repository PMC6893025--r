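PROTON <- 1.007276

test_that("adduct annotation recovers a planted neutral mass at ~0 ppm", {
  ref <- data.frame(id = c("LM1", "LM2"), name = c("x", "y"),
                    neutral_mass = c(100.000000, 750.123456))
  hits <- annotate_mass(100 + PROTON, "positive", ref)
  expect_equal(hits$id, "LM1")
  expect_equal(hits$adduct, "[M+H]+")
  expect_lt(abs(hits$ppm_error), 1e-6)
  # sodium adduct of the second entry
  hits2 <- annotate_mass(750.123456 + 22.989218, "positive", ref)
  expect_equal(hits2$id, "LM2")
  expect_equal(hits2$adduct, "[M+Na]+")
})

test_that("the 5 ppm annotation boundary is enforced", {
  ref <- data.frame(id = "LM1", name = "x", neutral_mass = 500)
  inside <- annotate_mass(500 * (1 + 4.8e-6) + PROTON, "positive", ref)
  outside <- annotate_mass(500 * (1 + 5.2e-6) + PROTON, "positive", ref)
  expect_equal(nrow(inside), 1)
  expect_lt(inside$ppm_error, 5)
  expect_equal(nrow(outside), 0)
})

test_that("ion-mode gating separates positive and negative adducts", {
  ref <- data.frame(id = "LM1", name = "x", neutral_mass = 300)
  # an [M-H]- ion never annotates in positive mode
  expect_equal(nrow(annotate_mass(300 - PROTON, "positive", ref)), 0)
  expect_equal(annotate_mass(300 - PROTON, "negative", ref)$adduct, "[M-H]-")
  expect_equal(annotate_mass(300 + 44.998201, "negative", ref)$adduct,
               "[M-H+HCOOH]-")
  expect_error(annotate_mass(300, "both", ref), "unknown ion mode")
})

test_that("matrix annotation tags every lipid within tolerance and flags ambiguity", {
  fx <- small_study()
  feat <- fx$dat$lipids_pos$features[1:20, ]
  ref <- data.frame(id = paste0("LM", 1:20), name = paste0("lip", 1:20),
                    neutral_mass = feat$mz - PROTON)
  ann <- annotate_matrix(im_subset(fx$dat$lipids_pos, compounds = 1:20), ref)
  expect_true(all(feat$compound_id %in% ann$compound_id))
  expect_true(all(abs(ann$ppm_error) <= 5))
  # two reference entries at the same mass produce flagged ambiguity
  ref2 <- data.frame(id = c("A", "DUP"), name = c("a", "dup"),
                     neutral_mass = rep(350.250000, 2))
  amb <- annotate_mass(350.25 + PROTON, "positive", ref2)
  expect_equal(nrow(amb), 2)
  expect_true(all(amb$ambiguous))
})

test_that("enrichment p-values are exact, order-invariant and BH-adjusted", {
  cg <- data.frame(compound_id = rep(paste0("c", 1:12), each = 1),
                   gene = paste0("g", 1:12))
  gp <- rbind(data.frame(gene = paste0("g", 1:4), pathway = "target"),
              data.frame(gene = paste0("g", 5:12), pathway = "rest"))
  fg <- paste0("c", 1:5)
  res <- hypergeom_enrichment(fg, paste0("c", 1:12), cg, gp)
  # exact upper-tail enumeration for the target pathway:
  # P(X >= 4) with 4 pathway genes, 8 others, 5 draws from 12
  p_exact <- sum(dhyper(4, 4, 8, 5))
  expect_equal(res$p[res$pathway == "target"], p_exact, tolerance = 1e-12)
  expect_equal(res$p_adj, bh_adjust(res$p), tolerance = 1e-12)
  # relabeling genes leaves p-values unchanged
  relabel <- setNames(paste0("h", 12:1), paste0("g", 1:12))
  cg2 <- cg; cg2$gene <- relabel[cg$gene]
  gp2 <- gp; gp2$gene <- relabel[gp$gene]
  res2 <- hypergeom_enrichment(fg, paste0("c", 1:12), cg2, gp2)
  expect_equal(res2$p[res2$pathway == "target"],
               res$p[res$pathway == "target"], tolerance = 1e-12)
})

test_that("foreground equal to background is never enriched", {
  cg <- data.frame(compound_id = paste0("c", 1:8), gene = paste0("g", 1:8))
  gp <- data.frame(gene = paste0("g", c(1:3, 4:8)),
                   pathway = rep(c("a", "b"), c(3, 5)))
  res <- hypergeom_enrichment(paste0("c", 1:8), paste0("c", 1:8), cg, gp)
  expect_true(all(res$p == 1))
  # foreground outside background is rejected
  expect_error(hypergeom_enrichment("c9", paste0("c", 1:8), cg, gp),
               "not in background")
})

test_that("a planted pathway concentration ranks first with small adjusted p", {
  set.seed(70)
  n_comp <- 120
  comp <- paste0("c", seq_len(n_comp))
  cg <- data.frame(compound_id = comp, gene = paste0("g", seq_len(n_comp)))
  # pathway pw_hit holds the genes of the first 25 compounds; 30 decoys
  pws <- c(list(data.frame(gene = paste0("g", 1:25), pathway = "pw_hit")),
           lapply(1:30, function(i) {
             data.frame(gene = paste0("g", sample(n_comp, 20)),
                        pathway = paste0("pw", i))
           }))
  gp <- do.call(rbind, pws)
  fg <- c(paste0("c", 1:20), paste0("c", sample(60:120, 5)))  # 20/25 in pw_hit
  res <- hypergeom_enrichment(fg, comp, cg, gp)
  expect_equal(res$pathway[1], "pw_hit")
  expect_lt(res$p_adj[1], 0.05)
  expect_true(res$significant[1])
})
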