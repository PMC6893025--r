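#' Standard adduct rules
#'
#' Mass offsets (Da, monoisotopic) applied to a neutral mass to obtain the
#' observed m/z of a singly charged adduct. Positive mode: [M+H]+, [M+Na]+,
#' [M+NH4]+; negative mode: [M-H]-, [M-H+HCOOH]- (formate), [M-H+CH3COOH]-
#' (acetate).
#'
#' @return data.frame with `name`, `ion_mode`, `offset`.
#' @export
adduct_rules <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+NH4]+",
             "[M-H]-", "[M-H+HCOOH]-", "[M-H+CH3COOH]-"),
    ion_mode = c("positive", "positive", "positive",
                 "negative", "negative", "negative"),
    offset = c(1.007276, 22.989218, 18.033823,
               -1.007276, 44.998201, 59.013851),
    stringsAsFactors = FALSE
  )
}

#' Adduct-aware mass annotation
#'
#' For each adduct rule matching the query's ionization mode, derives the
#' candidate neutral mass `mz - offset` (singly charged ions) and returns all
#' reference entries whose neutral monoisotopic mass lies within `ppm_tol`
#' parts per million of the candidate, tagged with the adduct and the signed
#' ppm error. A query matching several reference entries (or one entry via
#' several adducts) keeps all candidates.
#'
#' @param mz observed mass-to-charge ratio (Da).
#' @param ion_mode `"positive"` or `"negative"`.
#' @param reference data.frame with `id`, `name`, `neutral_mass` (Da) and
#'   optionally `class`.
#' @param ppm_tol mass tolerance in ppm.
#' @param rules adduct rule table, see [adduct_rules()].
#' @return data.frame of `id`, `name`, `adduct`, `neutral_mass`, `ppm_error`
#'   (zero rows when nothing matches).
#' @export
annotate_mass <- function(mz, ion_mode, reference, ppm_tol = 5,
                          rules = adduct_rules()) {
  if (!ion_mode %in% c("positive", "negative"))
    stop("unknown ion mode: ", ion_mode)
  stopifnot(is.numeric(mz), length(mz) == 1, mz > 0,
            all(c("id", "neutral_mass") %in% names(reference)))
  rules <- rules[rules$ion_mode == ion_mode, , drop = FALSE]
  hits <- list()
  for (r in seq_len(nrow(rules))) {
    cand_mass <- mz - rules$offset[r]
    if (cand_mass <= 0) next
    ppm <- (cand_mass - reference$neutral_mass) / reference$neutral_mass * 1e6
    hit <- which(abs(ppm) <= ppm_tol)
    if (length(hit) > 0)
      hits[[length(hits) + 1]] <- data.frame(
        id = reference$id[hit],
        name = if (!is.null(reference$name)) reference$name[hit] else NA_character_,
        adduct = rules$name[r],
        neutral_mass = reference$neutral_mass[hit],
        ppm_error = ppm[hit],
        stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(id = character(0), name = character(0),
                      adduct = character(0), neutral_mass = numeric(0),
                      ppm_error = numeric(0)))
  out <- do.call(rbind, hits)
  out$ambiguous <- nrow(out) > 1
  rownames(out) <- NULL
  out
}

#' Annotate every lipid feature of an intensity matrix
#'
#' @param m an `intensity_matrix` with lipid features.
#' @param reference neutral-mass reference table (see [annotate_mass()]).
#' @param ppm_tol mass tolerance in ppm.
#' @return data.frame of `compound_id` plus the [annotate_mass()] columns,
#'   one row per (feature, candidate) pair.
#' @export
annotate_matrix <- function(m, reference, ppm_tol = 5) {
  stopifnot(inherits(m, "intensity_matrix"))
  feat <- m$features[m$features$kind == "lipid", , drop = FALSE]
  res <- lapply(seq_len(nrow(feat)), function(i) {
    ann <- annotate_mass(feat$mz[i], feat$ion_mode[i], reference, ppm_tol)
    if (nrow(ann) == 0) return(NULL)
    cbind(compound_id = feat$compound_id[i], ann, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0)
    return(data.frame(compound_id = character(0), id = character(0),
                      name = character(0), adduct = character(0),
                      neutral_mass = numeric(0), ppm_error = numeric(0),
                      ambiguous = logical(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Hypergeometric pathway enrichment
#'
#' Tests, for every pathway, whether genes linked to the foreground compounds
#' are over-represented among genes linked to any background compound. The
#' gene universe is the union of genes linked to background compounds; the
#' draw is the union of genes linked to foreground compounds; the upper-tail
#' p-value is `P(X >= overlap)` with X hypergeometric. A compound with
#' several annotations contributes the union of its linked genes; genes in no
#' pathway contribute to the universe only. P-values are BH-adjusted across
#' pathways.
#'
#' @param foreground compound ids of interest (must be a subset of
#'   `background`).
#' @param background all annotated compound ids.
#' @param compound_gene data.frame edge list `compound_id`, `gene`.
#' @param gene_pathway data.frame edge list `gene`, `pathway`.
#' @param alpha significance threshold on adjusted p-values (stored on the
#'   result; all pathways are returned).
#' @return data.frame of `pathway`, `n_pathway` (universe genes in pathway),
#'   `n_overlap`, `overlap_genes`, `p`, `p_adj`, `significant`, ordered by p.
#' @export
hypergeom_enrichment <- function(foreground, background, compound_gene,
                                 gene_pathway, alpha = 0.05) {
  stopifnot(all(c("compound_id", "gene") %in% names(compound_gene)),
            all(c("gene", "pathway") %in% names(gene_pathway)))
  extra <- setdiff(foreground, background)
  if (length(extra) > 0)
    stop("foreground compound(s) not in background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  universe <- unique(compound_gene$gene[compound_gene$compound_id %in% background])
  if (length(universe) == 0) stop("empty gene universe")
  fg_genes <- unique(compound_gene$gene[compound_gene$compound_id %in% foreground])
  gp <- gene_pathway[gene_pathway$gene %in% universe, , drop = FALSE]
  pathways <- split(gp$gene, gp$pathway)
  pathways <- pathways[lengths(pathways) > 0]
  if (length(pathways) == 0) stop("no pathway contains a universe gene")
  res <- lapply(names(pathways), function(pw) {
    pw_genes <- unique(pathways[[pw]])
    ov <- intersect(pw_genes, fg_genes)
    p <- stats::phyper(length(ov) - 1, length(pw_genes),
                       length(universe) - length(pw_genes),
                       length(fg_genes), lower.tail = FALSE)
    data.frame(pathway = pw, n_pathway = length(pw_genes),
               n_overlap = length(ov),
               overlap_genes = paste(sort(ov), collapse = ","),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe_size") <- length(universe)
  attr(out, "foreground_size") <- length(fg_genes)
  out
}
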