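#' scGAD gene scores: raw contacts over gene bodies
#'
#' The single-cell gene associating domain (scGAD) score of gene j in cell i
#' is the raw number of contacts with at least one anchor's 10 kb bin
#' overlapping the gene body. It proxies expression and lets chromatin
#' profiles be co-embedded with RNA data.
#'
#' @param set an `sc_cellset` at 10 kb resolution.
#' @param genes tibble `chrom`, `start`, `end`, `gene` (1-based inclusive).
#' @return tibble `barcode`, `gene`, `score` (zero rows omitted); use
#'   [tidyr::pivot_wider()] or [gad_matrix()] for a dense cell-by-gene
#'   matrix.
#' @export
gad_scores <- function(set, genes) {
  gb <- genome_bins(set$genome)
  gene_bins <- lapply(seq_len(nrow(genes)), function(k) {
    gb$bin[gb$chrom == genes$chrom[k] &
             gb$end >= genes$start[k] & gb$start <= genes$end[k]]
  })
  names(gene_bins) <- genes$gene
  ct <- set$contacts
  out <- lapply(names(gene_bins), function(gname) {
    bins <- gene_bins[[gname]]
    hit <- ct$bin1 %in% bins | ct$bin2 %in% bins
    if (!any(hit)) return(NULL)
    ct[hit, ] |>
      dplyr::count(.data$barcode, wt = .data$count, name = "score") |>
      dplyr::mutate(gene = gname)
  })
  dplyr::bind_rows(out) |>
    dplyr::select("barcode", "gene", "score")
}

#' Dense cell-by-gene scGAD matrix
#' @param scores long tibble from [gad_scores()].
#' @param barcodes,genes row/column universes (defaults: those observed).
#' @return numeric matrix cells x genes.
#' @export
gad_matrix <- function(scores, barcodes = sort(unique(scores$barcode)),
                       genes = sort(unique(scores$gene))) {
  m <- matrix(0, length(barcodes), length(genes),
              dimnames = list(barcodes, genes))
  m[cbind(match(scores$barcode, barcodes), match(scores$gene, genes))] <-
    scores$score
  m
}

#' k-NN label transfer with standardized neighbor scores
#'
#' Each query cell's k nearest reference neighbours (Euclidean distance in a
#' shared embedding) receive standardized scores
#' D_m = (1/(d_m + eps)) / sum(1/(d + eps)) — summing to 1, with the closest
#' neighbour scoring highest — and the query is assigned the label with the
#' highest summed score.
#'
#' @param query numeric matrix, query cells x embedding dims (rownames =
#'   barcodes).
#' @param reference numeric matrix, reference cells x the same dims.
#' @param ref_labels labels, one per reference row.
#' @param k number of neighbours (default 15).
#' @param eps distance regulariser.
#' @return list with `assignments` (tibble `barcode`, `label`, `score`) and
#'   `neighbors` (tibble `barcode`, `neighbor`, `distance`, `weight`,
#'   `neighbor_label`).
#' @export
transfer_labels <- function(query, reference, ref_labels, k = 15,
                            eps = 1e-8) {
  if (k > nrow(reference)) stop("k exceeds the reference size")
  stopifnot(length(ref_labels) == nrow(reference))
  qn <- rownames(query) %||% as.character(seq_len(nrow(query)))
  nb <- lapply(seq_len(nrow(query)), function(i) {
    d2 <- colSums((t(reference) - query[i, ])^2)
    ord <- order(d2)[seq_len(k)]
    d <- sqrt(d2[ord])
    w <- (1 / (d + eps)) / sum(1 / (d + eps))
    tibble::tibble(barcode = qn[i], neighbor = ord, distance = d, weight = w,
                   neighbor_label = ref_labels[ord])
  })
  neighbors <- dplyr::bind_rows(nb)
  assignments <- neighbors |>
    dplyr::group_by(.data$barcode, .data$neighbor_label) |>
    dplyr::summarise(score = sum(.data$weight), .groups = "drop_last") |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::rename(label = "neighbor_label")
  list(assignments = assignments, neighbors = neighbors)
}

#' Overlap coefficients between two annotations through co-embedding clusters
#'
#' Validates a query annotation A against a reference annotation B via
#' shared co-embedding clusters C:
#' O_ij = max over clusters k of min(|A_i n C_k| / |A_i|, |B_j n C_k| / |B_j|).
#'
#' @param labels_a named vector: query cells -> annotation A.
#' @param labels_b named vector: reference cells -> annotation B.
#' @param clusters named vector over the union of cells -> cluster id.
#' @return matrix O with rownames = levels of A, colnames = levels of B.
#' @export
overlap_coefficients <- function(labels_a, labels_b, clusters) {
  a_lv <- sort(unique(labels_a)); b_lv <- sort(unique(labels_b))
  k_lv <- sort(unique(clusters))
  O <- matrix(0, length(a_lv), length(b_lv), dimnames = list(a_lv, b_lv))
  for (i in seq_along(a_lv)) {
    ai <- names(labels_a)[labels_a == a_lv[i]]
    for (j in seq_along(b_lv)) {
      bj <- names(labels_b)[labels_b == b_lv[j]]
      vals <- vapply(k_lv, function(kk) {
        ck <- names(clusters)[clusters == kk]
        min(length(intersect(ai, ck)) / length(ai),
            length(intersect(bj, ck)) / length(bj))
      }, numeric(1))
      O[i, j] <- max(vals)
    }
  }
  O
}

#' Signature scores with expression-matched control gene sets
#'
#' The score of state j in cell i is the mean expression of the signature
#' genes G_j minus the mean expression of a control set G_jcont drawn to
#' match the signature's expression level: genes are ranked by average
#' expression and cut into `n_bins` bins, and each signature gene
#' contributes `n_ctrl` genes sampled (seeded) from its own bin. Signature
#' genes (of any state) are excluded from control pools; if a bin holds
#' nothing else, the nearest non-signature genes by average expression are
#' used instead.
#'
#' @param expr normalized expression matrix, cells x genes.
#' @param gene_sets named list of character vectors (e.g. OPC/NPC/AC/MES
#'   signatures); genes absent from `expr` are dropped with a warning.
#' @param n_bins number of average-expression bins (default 30).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return tibble `barcode` plus one score column per state.
#' @export
state_scores <- function(expr, gene_sets, n_bins = 30, n_ctrl = 100,
                         seed = 1) {
  set.seed(seed)
  avg <- colMeans(expr)
  br <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins)
  names(br) <- colnames(expr)
  out <- tibble::tibble(barcode = rownames(expr) %||%
                          as.character(seq_len(nrow(expr))))
  for (state in names(gene_sets)) {
    gs <- gene_sets[[state]]
    missing <- setdiff(gs, colnames(expr))
    if (length(missing) > 0) {
      warning(length(missing), " ", state, " genes absent from the matrix")
      gs <- setdiff(gs, missing)
    }
    if (length(gs) == 0) stop("no ", state, " signature genes in the matrix")
    all_sig <- unique(unlist(gene_sets))
    ctrl <- unlist(lapply(gs, function(g) {
      pool <- setdiff(names(br)[br == br[g]], all_sig)
      if (length(pool) == 0) {
        nonsig <- setdiff(names(br), all_sig)
        pool <- nonsig[order(abs(avg[nonsig] - avg[g]))]
        pool <- pool[seq_len(min(n_ctrl, length(pool)))]
      }
      sample(pool, min(n_ctrl, length(pool)))
    }))
    sc <- rowMeans(expr[, gs, drop = FALSE]) -
      rowMeans(expr[, ctrl, drop = FALSE])
    out[[state]] <- unname(sc)
  }
  out
}

#' Project four-state scores onto the (D, identity) plane
#'
#' D = max(SC_OPC, SC_NPC) - max(SC_AC, SC_MES) splits cells into the
#' OPC/NPC half (D > 0) and the AC/MES half. Within the winning pair the
#' identity value is log2(|SC_a - SC_b| + 1), signed positive toward the
#' first state of the pair (OPC, respectively AC). The quadrant is the
#' winning state.
#'
#' @param scores tibble from [state_scores()] with columns `OPC`, `NPC`,
#'   `AC`, `MES` (plus `barcode`).
#' @return `scores` with added `D`, `identity`, `quadrant` columns.
#' @export
state_projection <- function(scores) {
  stopifnot(all(c("OPC", "NPC", "AC", "MES") %in% names(scores)))
  D <- pmax(scores$OPC, scores$NPC) - pmax(scores$AC, scores$MES)
  top <- D > 0
  mag <- ifelse(top, log2(abs(scores$OPC - scores$NPC) + 1),
                log2(abs(scores$AC - scores$MES) + 1))
  sign_ <- ifelse(top, sign(scores$OPC - scores$NPC),
                  sign(scores$AC - scores$MES))
  quadrant <- ifelse(
    top, ifelse(scores$OPC >= scores$NPC, "OPC", "NPC"),
    ifelse(scores$AC >= scores$MES, "AC", "MES")
  )
  dplyr::mutate(scores, D = D, identity = mag * sign_, quadrant = quadrant)
}

#' Neighbor-weighted state scores for chromatin-profiled cells
#'
#' For a cell annotated by k-NN transfer, the Hi-C state score is the
#' convex combination of the neighbours' state scores under the
#' standardized weights: HSC_j(i) = sum_g SC_j(g) * D_m(g).
#'
#' @param neighbors tibble from [transfer_labels()] (`barcode`, `neighbor`,
#'   `weight`).
#' @param neighbor_scores tibble/data frame of reference state scores, rows
#'   indexed by neighbor position (one row per reference cell), columns =
#'   states.
#' @param states columns of `neighbor_scores` to aggregate.
#' @return tibble `barcode` plus one HSC column per state.
#' @export
hic_state_scores <- function(neighbors, neighbor_scores,
                             states = c("OPC", "NPC", "AC", "MES")) {
  stopifnot(all(states %in% names(neighbor_scores)))
  out <- lapply(split(neighbors, neighbors$barcode), function(df) {
    sc <- vapply(states, function(s)
      sum(neighbor_scores[[s]][df$neighbor] * df$weight), numeric(1))
    tibble::as_tibble(c(list(barcode = df$barcode[1]), as.list(sc)))
  })
  dplyr::bind_rows(out)
}
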