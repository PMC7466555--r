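# absolute quantification (total protein approach), differential protein
# allocation, PCA, reporter metabolites and proteome allocation profiles

#' Read a proteomics intensity table from TSV
#'
#' @param path TSV with columns `protein_id`, `condition`, `replicate`,
#'   `light_intensity`, `heavy_intensity`.
#' @return validated data frame.
#' @export
read_intensities <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           fileEncoding = "UTF-8")
  need <- c("protein_id", "condition", "replicate", "light_intensity",
            "heavy_intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$light_intensity < 0, na.rm = TRUE) ||
      any(tab$heavy_intensity < 0, na.rm = TRUE)) {
    stop("negative intensities")
  }
  key <- paste(tab$protein_id, tab$condition, tab$replicate)
  if (anyDuplicated(key)) stop("duplicate (protein, condition, replicate) rows")
  tab
}

#' Absolute quantification by the total protein approach
#'
#' Converts intensities to absolute abundances: each protein's share of the
#' summed per-sample signal, scaled by the assumed fraction of the total
#' protein mass covered by the quantified proteins. With the 1:1
#' heavy-labelled internal standard (`mode = "ratio"`) the per-protein
#' light/heavy ratio, median-centred within the sample, is the quantitative
#' signal; `mode = "intensity"` uses the light intensities directly.
#'
#' @param intensities data frame as returned by [read_intensities()] or
#'   [generate_proteome()].
#' @param coverage assumed fraction of total protein mass covered
#'   (default 0.90).
#' @param total_protein optional total protein content (g/gDCW); when
#'   given, a `per_dcw` column (ug/gDCW) is added.
#' @param mode `"ratio"` (default) or `"intensity"`.
#' @return object of class `protein_quant`: data frame with columns
#'   `protein_id`, `condition`, `replicate`, `abundance` (ug per g total
#'   protein); per sample the abundances sum to `coverage * 1e6`.
#' @export
tpa_quantify <- function(intensities, coverage = 0.90, total_protein = NULL,
                         mode = c("ratio", "intensity")) {
  mode <- match.arg(mode)
  tab <- intensities
  sample_id <- paste(tab$condition, tab$replicate, sep = "|")
  out <- do.call(rbind, lapply(split(tab, sample_id), function(s) {
    signal <- if (mode == "ratio") {
      ok <- s$heavy_intensity > 0
      r <- ifelse(ok, s$light_intensity / pmax(s$heavy_intensity, 1e-300), 0)
      med <- stats::median(r[ok & s$light_intensity > 0])
      if (is.finite(med) && med > 0) r / med else r
    } else {
      s$light_intensity
    }
    tot <- sum(signal)
    if (tot <= 0) stop("all-zero sample: ", s$condition[1], " replicate ",
                       s$replicate[1])
    data.frame(protein_id = s$protein_id, condition = s$condition,
               replicate = s$replicate,
               abundance = coverage * signal / tot * 1e6,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(total_protein)) {
    out$per_dcw <- out$abundance * total_protein
  }
  class(out) <- c("protein_quant", "data.frame")
  out
}

quant_matrix <- function(quant) {
  sample_id <- paste(quant$condition, quant$replicate, sep = "|")
  stats::xtabs(abundance ~ protein_id + sample_id, data =
                 cbind(quant, sample_id = sample_id))
}

log2_with_floor <- function(M) {
  # floor at half the smallest positive abundance of each sample
  for (j in seq_len(ncol(M))) {
    pos <- M[, j] > 0
    if (!any(pos)) stop("sample with no positive abundances")
    M[!pos, j] <- min(M[pos, j]) / 2
  }
  log2(M)
}

#' Differential protein allocation between two conditions
#'
#' Welch two-sided t-test on log2 abundances (floored at half the smallest
#' positive per-sample abundance), with Benjamini-Hochberg adjustment over
#' all tested proteins.
#'
#' @param quant a [tpa_quantify()] result.
#' @param contrast character of length 2: `c(condition_A, condition_B)`;
#'   fold changes are `log2(B) - log2(A)`.
#' @return object of class `de_result`: data frame with `protein_id`,
#'   `mean_A`, `mean_B`, `log2fc`, `p`, `adj_p`; proteins without variance
#'   in both groups get `p = 1` at zero fold change.
#' @export
differential_allocation <- function(quant, contrast) {
  stopifnot(length(contrast) == 2)
  sub <- quant[quant$condition %in% contrast, , drop = FALSE]
  if (!all(contrast %in% sub$condition)) {
    stop("contrast condition(s) absent from the quant table")
  }
  for (cond in contrast) {
    if (length(unique(sub$replicate[sub$condition == cond])) < 2) {
      stop("need >= 2 replicates per condition")
    }
  }
  M <- quant_matrix(sub)
  L <- log2_with_floor(M)
  # abundances are shares of a fixed total, so a genuine rise of one group
  # depresses every other share; median-centring per sample reports
  # allocation changes relative to the typical protein instead
  L <- sweep(L, 2, apply(L, 2, stats::median))
  conds <- sub("\\|.*", "", colnames(L))
  A <- L[, conds == contrast[1], drop = FALSE]
  B <- L[, conds == contrast[2], drop = FALSE]
  res <- t(vapply(seq_len(nrow(L)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    lfc <- mean(b) - mean(a)
    p <- if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12) {
      if (abs(lfc) < 1e-12) 1 else 0
    } else {
      tryCatch(stats::t.test(b, a)$p.value, error = function(e) 1)
    }
    c(mean_A = mean(a), mean_B = mean(b), log2fc = lfc, p = p)
  }, numeric(4)))
  out <- data.frame(protein_id = rownames(L), res, stringsAsFactors = FALSE)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

#' Principal component analysis of proteome samples
#'
#' PCA on unit-variance-scaled log2 abundances; samples are observations.
#'
#' @param quant a [tpa_quantify()] result.
#' @return list with `scores` (samples x components), `explained`
#'   (variance fractions) and the condition of each sample.
#' @export
pca_samples <- function(quant) {
  M <- quant_matrix(quant)
  if (ncol(M) < 3) stop("need at least 3 samples for PCA")
  L <- t(log2_with_floor(M))
  keep <- apply(L, 2, stats::sd) > 1e-12
  if (!any(keep)) stop("constant abundance matrix")
  pc <- stats::prcomp(L[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = expl,
       condition = sub("\\|.*", "", rownames(L)))
}

#' Reporter-metabolite analysis
#'
#' Scores each metabolite of the model's enzyme-metabolite graph by the
#' coordinated expression change of its neighbouring enzymes: per-protein
#' Z-scores from the differential test are aggregated as
#' `Z_met = sum(Z_i)/sqrt(k)` and corrected against the mean and SD of
#' `n_background` random size-k draws from all scored proteins.
#'
#' @param de a [differential_allocation()] result; `protein_id` must map to
#'   model gene ids.
#' @param model a [core_model()] (source of the enzyme-metabolite
#'   adjacency).
#' @param direction `"up"` (Z signed by fold change), `"down"` (sign
#'   flipped) or `"distinct"` (unsigned, two-sided p).
#' @param n_background random draws per neighbourhood size
#'   (default 1000).
#' @param seed RNG seed for the background draws.
#' @return object of class `reporter_scores`: data frame with `metabolite`,
#'   `k`, `z`, `z_corrected`, `p`, ordered by decreasing corrected Z.
#' @export
reporter_metabolites <- function(de, model, direction = c("up", "down",
                                                          "distinct"),
                                 n_background = 1000, seed = 1) {
  direction <- match.arg(direction)
  adj <- enzyme_metabolite_adjacency(model)
  gene_z <- reporter_gene_z(de, direction)
  genes <- names(gene_z)
  with_seed(seed, {
    rows <- lapply(names(adj), function(met) {
      nb <- intersect(adj[[met]], genes)
      k <- length(nb)
      if (k == 0L) return(NULL)
      z <- sum(gene_z[nb]) / sqrt(k)
      data.frame(metabolite = met, k = k, z = z, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) stop("no metabolite has scored neighbour enzymes")
    out <- do.call(rbind, rows)
    # background correction per neighbourhood size
    for (k in sort(unique(out$k))) {
      draws <- vapply(seq_len(n_background), function(i)
        sum(gene_z[sample.int(length(gene_z), k)]) / sqrt(k), 0)
      sel <- out$k == k
      out$z_corrected[sel] <- (out$z[sel] - mean(draws)) / stats::sd(draws)
    }
    out$p <- stats::pnorm(out$z_corrected, lower.tail = FALSE)
    out <- out[order(-out$z_corrected), ]
    rownames(out) <- NULL
    attr(out, "direction") <- direction
    class(out) <- c("reporter_scores", "data.frame")
    out
  })
}

reporter_gene_z <- function(de, direction) {
  p <- pmin(pmax(de$p, 1e-15), 1 - 1e-15)
  z <- switch(direction,
    up = sign(de$log2fc) * stats::qnorm(1 - p / 2),
    down = -sign(de$log2fc) * stats::qnorm(1 - p / 2),
    distinct = stats::qnorm(1 - p)
  )
  stats::setNames(z, de$protein_id)
}

#' Proteome allocation profile
#'
#' Mass fraction of the quantified proteome per functional category, and
#' the cumulative share of the N most abundant proteins.
#'
#' @param quant a [tpa_quantify()] result.
#' @param category_map data frame with columns `protein_id`, `category`;
#'   proteins not covered fall into `"other"`.
#' @param top_n size of the top-abundance group (default 100).
#' @return object of class `allocation_profile`: list with `fractions`
#'   (condition x category data frame, rows summing to 1) and `top_share`
#'   (named vector per sample).
#' @export
allocation_profile <- function(quant, category_map, top_n = 100) {
  stopifnot(all(c("protein_id", "category") %in% names(category_map)))
  cat_of <- stats::setNames(category_map$category, category_map$protein_id)
  sample_id <- paste(quant$condition, quant$replicate, sep = "|")
  fr <- lapply(split(quant, sample_id), function(s) {
    cats <- cat_of[s$protein_id]
    cats[is.na(cats)] <- "other"
    tot <- sum(s$abundance)
    frac <- tapply(s$abundance, cats, sum) / tot
    top <- sum(sort(s$abundance, decreasing = TRUE)[seq_len(
      min(top_n, nrow(s)))]) / tot
    list(frac = frac, top = top)
  })
  all_cats <- sort(unique(unlist(lapply(fr, function(x) names(x$frac)))))
  tab <- do.call(rbind, lapply(fr, function(x) {
    v <- stats::setNames(rep(0, length(all_cats)), all_cats)
    v[names(x$frac)] <- x$frac
    v
  }))
  structure(list(fractions = as.data.frame(tab),
                 top_share = vapply(fr, `[[`, 0, "top"),
                 top_n = top_n),
            class = "allocation_profile")
}

#' Derive a protein category map from model subsystems
#'
#' Maps every gene of the model to a coarse functional category based on
#' the subsystem of the reactions it catalyses; intended as an editable
#' starting point for [allocation_profile()].
#'
#' @param model a [core_model()].
#' @return data frame with `protein_id`, `category`.
#' @export
category_map_from_model <- function(model) {
  g2r <- gene_reaction_map(model)
  cat_of_subsystem <- function(ss) {
    if (grepl("Glycolysis", ss)) return("glycolysis")
    if (grepl("Lipid", ss)) return("lipid metabolism")
    if (grepl("TCA|Oxidative phosphorylation", ss)) return("mitochondria")
    if (grepl("Nitrogen|Protein", ss)) return("amino-acid metabolism")
    "other"
  }
  rows <- lapply(names(g2r), function(g) {
    ss <- vapply(g2r[[g]], function(rid) model$reactions[[rid]]$subsystem, "")
    cats <- vapply(ss, cat_of_subsystem, "")
    data.frame(protein_id = g,
               category = names(sort(table(cats), decreasing = TRUE))[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
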