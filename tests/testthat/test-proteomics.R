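# total-protein-approach quantification, differential allocation, PCA,
# reporter metabolites and allocation profiles

two_protein_table <- function(l1, l2, h1 = 1, h2 = 1) {
  data.frame(protein_id = c("A", "B"), condition = "C1", replicate = 1L,
             light_intensity = c(l1, l2), heavy_intensity = c(h1, h2))
}

test_that("equal signals split the covered proteome mass equally", {
  q <- tpa_quantify(two_protein_table(5000, 5000), coverage = 0.9)
  expect_equal(q$abundance, c(450000, 450000))
})

test_that("zero-intensity proteins get zero abundance", {
  q <- tpa_quantify(two_protein_table(0, 5000), coverage = 0.9)
  expect_equal(q$abundance[q$protein_id == "A"], 0)
  expect_equal(q$abundance[q$protein_id == "B"], 900000)
})

test_that("all-zero samples are rejected", {
  expect_error(tpa_quantify(two_protein_table(0, 0)), "all-zero")
})

test_that("per-sample abundances always total the covered mass exactly", {
  pg <- generate_proteome(proteome_config(n_proteins = 200), seed = 8)
  for (mode in c("ratio", "intensity")) {
    q <- tpa_quantify(pg$intensities, coverage = 0.9, mode = mode)
    sums <- tapply(q$abundance, paste(q$condition, q$replicate), sum)
    expect_true(all(abs(sums - 0.9e6) < 1e-3))
  }
})

test_that("known ground-truth mass fractions are recovered proportionally", {
  cfg <- proteome_config(n_proteins = 300, cv = 0, replicates = 1,
                         affected = list())
  pg <- generate_proteome(cfg, seed = 2)
  q <- tpa_quantify(pg$intensities, coverage = 0.9, mode = "intensity")
  one <- q[q$condition == cfg$conditions[1], ]
  truth <- pg$truth$mass_fraction[one$protein_id]
  expect_equal(stats::cor(one$abundance, truth, method = "spearman"), 1)
  expect_equal(one$abundance, 0.9e6 * unname(truth), tolerance = 1e-9)
})

test_that("per-DCW abundances scale by total protein content", {
  q <- tpa_quantify(two_protein_table(1000, 3000), coverage = 0.9,
                    total_protein = 0.48)
  expect_equal(q$per_dcw, q$abundance * 0.48)
})

test_that("identical groups give zero fold change and unit p-values", {
  tab <- expand.grid(protein_id = c("A", "B", "C"),
                     condition = c("X", "Y"), replicate = 1:3)
  tab$light_intensity <- rep(c(100, 200, 400), 6)
  tab$heavy_intensity <- 1
  de <- differential_allocation(tpa_quantify(tab), c("X", "Y"))
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$p, rep(1, 3))
  expect_equal(de$adj_p, rep(1, 3))
})

test_that("BH adjustment reproduces the hand-worked example", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               c(0.04, 0.04, 0.04, 0.04))
})

test_that("adjusted p-values dominate raw ones and are rank-monotone", {
  pg <- generate_proteome(proteome_config(n_proteins = 400), seed = 3)
  de <- differential_allocation(tpa_quantify(pg$intensities),
                                c("N_excess", "N_limited"))
  expect_true(all(de$adj_p >= de$p - 1e-12))
  ord <- order(de$p)
  expect_true(all(diff(de$adj_p[ord]) > -1e-12))
  # thresholding adjusted values again changes nothing
  expect_equal(stats::p.adjust(de$adj_p, "BH") < 0.01, de$adj_p < 0.01)
})

test_that("a null proteome produces no discoveries beyond the FDR budget", {
  cfg <- proteome_config(n_proteins = 1000, affected = list())
  pg <- generate_proteome(cfg, seed = 11)
  de <- differential_allocation(tpa_quantify(pg$intensities),
                                cfg$conditions)
  expect_lte(sum(de$adj_p < 0.01), 3)
})

test_that("strong true effects are recovered with controlled FDR", {
  # three replicates bound the attainable p-values of a plain t-test:
  # a four-fold change clears the adjusted 1% threshold across 3000
  # proteins only when channel CVs are a few percent, the regime this
  # simulation pins down
  cfg <- proteome_config(n_proteins = 3000, cv = 0.03, replicates = 3,
                         affected = list(list(proteins = 100, log2fc = 2,
                                              condition = "N_limited")))
  pg <- generate_proteome(cfg, seed = 13)
  de <- differential_allocation(tpa_quantify(pg$intensities),
                                cfg$conditions)
  affected <- names(pg$truth$affected_by_condition$N_limited)
  ups <- de$protein_id[de$adj_p < 0.01 & de$log2fc > 0]
  expect_gte(mean(affected %in% ups), 0.90)
  expect_lte(sum(!(ups %in% affected)) / max(length(ups), 1), 0.03)
})

test_that("missing conditions and single replicates are rejected", {
  tab <- two_protein_table(100, 200)
  q <- tpa_quantify(tab)
  expect_error(differential_allocation(q, c("C1", "C9")), "absent")
})

test_that("PCA separates a strong two-group design on the first component", {
  cfg <- proteome_config(n_proteins = 500, cv = 0.1,
                         affected = list(list(proteins = 150, log2fc = 3,
                                              condition = "N_limited")))
  pg <- generate_proteome(cfg, seed = 21)
  pc <- pca_samples(tpa_quantify(pg$intensities))
  groups <- split(pc$scores[, 1], pc$condition)
  expect_true(max(groups[[1]]) < min(groups[[2]]) ||
                max(groups[[2]]) < min(groups[[1]]))
  expect_true(all(diff(pc$explained) < 1e-9))
  expect_lte(sum(pc$explained), 1 + 1e-9)
})

test_that("constant abundance matrices cannot be decomposed", {
  tab <- expand.grid(protein_id = c("A", "B"), condition = "X",
                     replicate = 1:3)
  tab$light_intensity <- 100
  tab$heavy_intensity <- 1
  expect_error(pca_samples(tpa_quantify(tab)), "constant")
})

test_that("a single neighbour passes its Z-score through unchanged", {
  m <- load_model(core_model_path())
  # craft a differential result with known Z for the phosphoketolase gene
  genes <- names(gene_reaction_map(m))
  z_target <- 3
  p <- rep(0.5, length(genes))
  lfc <- rep(1, length(genes))
  p[genes == "RHTO_04463"] <- 2 * (1 - stats::pnorm(z_target))
  de <- data.frame(protein_id = genes, log2fc = lfc, p = p)
  rs <- reporter_metabolites(de, m, direction = "up", n_background = 200,
                             seed = 2)
  # acetyl phosphate touches only the PK/PTA neighbourhood
  acp <- rs[rs$metabolite == "acp_c", ]
  expect_equal(acp$k, 2)  # PK and PTA genes
  # a metabolite whose only scored neighbour is the shifted gene
  one <- rs[rs$k == 1 & rs$metabolite == "gap_c", ]
  uncorrected <- rs$z[rs$metabolite == "x5p_c"]
  expect_true(is.finite(uncorrected))
})

test_that("uncorrected reporter Z equals the neighbour Z at k = 1", {
  # minimal model: one gene on one reaction touching one scored metabolite
  mets <- data.frame(id = c("a_c", "b_c", "bio_e"),
                     name = c("a", "b", "bio"),
                     compartment = c("c", "c", "e"), formula = "",
                     charge = 0)
  rxns <- list(
    list(id = "R1", name = "R1", mets = c(a_c = -1, b_c = 1), lb = 0,
         ub = 10, subsystem = "", genes = "G1", pseudo = TRUE),
    list(id = "BIOMASS", name = "bio", mets = c(b_c = -1, bio_e = 1),
         lb = 0, ub = 10, subsystem = "", genes = character(0),
         pseudo = TRUE),
    list(id = "NGAM", name = "ngam", mets = c(a_c = -1), lb = 0, ub = 10,
         subsystem = "", genes = character(0), pseudo = TRUE),
    list(id = "EX_bio", name = "ex", mets = c(bio_e = -1), lb = 0, ub = 10,
         subsystem = "", genes = character(0), pseudo = TRUE))
  m <- core_model(mets, rxns, "BIOMASS", "NGAM")
  de <- data.frame(protein_id = "G1", log2fc = 1,
                   p = 2 * (1 - stats::pnorm(3)))
  rs <- reporter_metabolites(de, m, n_background = 100, seed = 1)
  expect_equal(rs$z[rs$metabolite == "a_c"], 3, tolerance = 1e-9)
  expect_equal(rs$k, c(1, 1))
})

test_that("corrected reporter Z is standard normal under permuted inputs", {
  m <- load_model(core_model_path())
  genes <- names(gene_reaction_map(m))
  set.seed(31)
  de <- data.frame(protein_id = genes,
                   log2fc = stats::rnorm(length(genes)),
                   p = stats::runif(length(genes)))
  rs <- reporter_metabolites(de, m, direction = "up", n_background = 1000,
                             seed = 7)
  expect_lt(abs(mean(rs$z_corrected)), 0.2)
  expect_lt(abs(stats::sd(rs$z_corrected) - 1), 0.25)
  # shared neighbourhoods tie some scores; deduplicate for the KS check
  ks <- stats::ks.test(unique(rs$z_corrected), "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("coordinated shifts around NAD surface it as a top reporter", {
  m <- load_model(core_model_path())
  genes <- names(gene_reaction_map(m))
  adj <- enzyme_metabolite_adjacency(m)
  nad_genes <- union(adj[["nad_c"]], adj[["nadh_c"]])
  set.seed(5)
  de <- data.frame(protein_id = genes,
                   log2fc = ifelse(genes %in% nad_genes, 1.5,
                                   stats::rnorm(length(genes), 0, 0.2)),
                   p = ifelse(genes %in% nad_genes, 1e-6,
                              stats::runif(length(genes))))
  rs <- reporter_metabolites(de, m, direction = "up", n_background = 500,
                             seed = 9)
  top <- rs$metabolite[seq_len(8)]
  expect_true(any(c("nad_c", "nadh_c") %in% top))
})

test_that("metabolites without scored neighbours are skipped", {
  m <- load_model(core_model_path())
  de <- data.frame(protein_id = "RHTO_04463", log2fc = 1, p = 0.001)
  rs <- reporter_metabolites(de, m, n_background = 100, seed = 1)
  expect_true(all(rs$k >= 1))
  expect_false("glu_c" %in% rs$metabolite)   # its genes are unscored
})

test_that("allocation fractions sum to one and respect the category map", {
  pg <- generate_proteome(proteome_config(n_proteins = 120), seed = 17)
  q <- tpa_quantify(pg$intensities)
  cmap <- data.frame(protein_id = sprintf("P%04d", 1:120),
                     category = rep(c("ribosome", "glycolysis", "other"),
                                    each = 40))
  prof <- allocation_profile(q, cmap, top_n = 10)
  expect_true(all(abs(rowSums(prof$fractions) - 1) < 1e-6))
  expect_true(all(prof$top_share > 0 & prof$top_share <= 1))
  # single-category map concentrates everything
  one <- allocation_profile(q, data.frame(protein_id = cmap$protein_id,
                                          category = "ribosome"))
  expect_true(all(abs(one$fractions$ribosome - 1) < 1e-9))
})

test_that("a constructed one-third ribosomal proteome is recovered", {
  # 40 ribosomal proteins carrying one-third of the total signal
  n <- 120
  ids <- sprintf("P%04d", 1:n)
  ribo <- ids[1:40]
  light <- rep(1e4, n)   # 40 of 120 equal-abundance proteins = 1/3
  tab <- data.frame(protein_id = ids, condition = "C", replicate = 1L,
                    light_intensity = light, heavy_intensity = 1)
  q <- tpa_quantify(tab, mode = "intensity")
  prof <- allocation_profile(q, data.frame(protein_id = ribo,
                                           category = "ribosome"))
  expect_equal(prof$fractions$ribosome, 1 / 3, tolerance = 1e-9)
})

test_that("proteome generation is reproducible and respects conflicts", {
  cfg <- proteome_config(n_proteins = 100)
  a <- generate_proteome(cfg, seed = 4)
  b <- generate_proteome(cfg, seed = 4)
  expect_identical(a$intensities, b$intensities)
  c <- generate_proteome(cfg, seed = 5)
  expect_false(identical(a$intensities, c$intensities))
  bad <- proteome_config(n_proteins = 100, affected = list(
    list(proteins = c("P0001"), log2fc = 2, condition = "N_limited"),
    list(proteins = c("P0001"), log2fc = -1, condition = "N_limited")))
  expect_error(generate_proteome(bad, seed = 1), "conflicting")
})
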