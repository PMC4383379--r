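# Identity-scaled RMSD between helix-oligomer models, pairwise matrices
# and threshold grouping used to pick representative structures.

backbone_region <- function(model, region, chains = NULL) {
  at <- model$atoms
  if (is.null(chains)) chains <- sort(unique(at$chain))
  at <- at[at$chain %in% chains & at$elety %in% c("N", "CA", "C", "O"), ,
           drop = FALSE]
  at[at$resno >= region[1] & at$resno <= region[2], , drop = FALSE]
}

# residue correspondence between two models for one chain pairing:
# identical residue types at equal renumbered positions within region
identity_pairs <- function(a, b, region) {
  seq_tab <- function(at) {
    u <- unique(at[, c("chain", "resno", "resid")])
    u[order(u$chain, u$resno), ]
  }
  ta <- seq_tab(a); tb <- seq_tab(b)
  key <- function(t) paste(t$chain, t$resno)
  m <- merge(ta, tb, by.x = c("chain", "resno"), by.y = c("chain", "resno"))
  m <- m[m$resid.x == m$resid.y, c("chain", "resno")]
  m[order(m$chain, m$resno), ]
}

swap_chains <- function(model) {
  chains <- sort(unique(model$atoms$chain))
  if (length(chains) != 2) return(NULL)
  at <- model$atoms
  at$chain <- ifelse(at$chain == chains[1], chains[2], chains[1])
  at <- at[order(at$chain, at$resno), ]
  structure_model(at, model_id = model$model_id, metadata = model$metadata)
}

.nrmsd_one <- function(model_a, model_b, aligned_pairs, region) {
  bb_a <- backbone_region(model_a, region)
  bb_b <- backbone_region(model_b, region)
  n_bb <- c(nrow(bb_a), nrow(bb_b))
  if (is.null(aligned_pairs)) {
    aligned_pairs <- identity_pairs(bb_a, bb_b, region)
  }
  if (nrow(aligned_pairs) < 3) {
    stop("input error: fewer than 3 aligned residue pairs", call. = FALSE)
  }
  key <- function(at) paste(at$chain, at$resno, at$elety)
  pk <- paste(aligned_pairs$chain, aligned_pairs$resno)
  sel_a <- bb_a[paste(bb_a$chain, bb_a$resno) %in% pk, , drop = FALSE]
  sel_b <- bb_b[paste(bb_b$chain, bb_b$resno) %in% pk, , drop = FALSE]
  sel_a <- sel_a[order(sel_a$chain, sel_a$resno, sel_a$elety), ]
  sel_b <- sel_b[order(sel_b$chain, sel_b$resno, sel_b$elety), ]
  if (!identical(key(sel_a), key(sel_b))) {
    stop("input error: aligned pairs do not resolve to matching backbone atoms",
         call. = FALSE)
  }
  xa <- as.matrix(sel_a[, c("x", "y", "z")])
  xb <- as.matrix(sel_b[, c("x", "y", "z")])
  fit <- kabsch_fit(xa, xb)
  rmsd_align <- rmsd_xyz(fit$xyz, xb)
  n_a <- c(nrow(sel_a), nrow(sel_b))
  list(rmsd_align = rmsd_align,
       rmsd_norm = rmsd_align * sum(n_bb) / sum(n_a),
       n_backbone = n_bb, n_aligned = n_a)
}

#' Identity-scaled (normalized) RMSD between two models
#'
#' Best-fit backbone RMSD over the residues that are identical between the
#' two models (equal residue type at equal renumbered position within the
#' compared region), scaled up by the fraction of backbone atoms that could
#' not be used:
#' `rmsd_norm = rmsd_align * (N_bb,1 + N_bb,2) / (N_a,1 + N_a,2)`,
#' where `N_bb` counts all backbone atoms of the compared regions and `N_a`
#' those entering the superposition. The scaling penalizes comparisons
#' resting on few identical residues, making values comparable across
#' homologous helix pairs of different sequence similarity. Superposition
#' is a plain least-squares fit with no outlier rejection. For two-chain
#' models both chain pairings (A-A/B-B and A-B/B-A) are evaluated and the
#' smaller `rmsd_norm` kept, since homodimer chain labels are arbitrary.
#'
#' @param model_a,model_b [structure_model()] objects, renumbered so that
#'   equivalent residues share indices.
#' @param aligned_pairs optional explicit correspondence (data.frame with
#'   `chain`, `resno`) overriding the identity rule.
#' @param region central-residue range (renumbered) entering the
#'   comparison; default `c(11, 25)`, the central region of TM helices with
#'   flanking extensions.
#' @return list with `rmsd_align`, `rmsd_norm` (A), atom counts and the
#'   chain pairing used.
#' @export
normalized_rmsd <- function(model_a, model_b, aligned_pairs = NULL,
                            region = c(11, 25)) {
  stopifnot(inherits(model_a, "structure_model"),
            inherits(model_b, "structure_model"))
  res <- .nrmsd_one(model_a, model_b, aligned_pairs, region)
  res$chain_pairing <- "direct"
  if (is.null(aligned_pairs)) {
    swapped <- swap_chains(model_b)
    if (!is.null(swapped)) {
      alt <- tryCatch(.nrmsd_one(model_a, swapped, NULL, region),
                      error = function(e) NULL)
      if (!is.null(alt) && alt$rmsd_norm < res$rmsd_norm) {
        res <- alt
        res$chain_pairing <- "swapped"
      }
    }
  }
  res
}

#' Pairwise normalized-RMSD matrix over a model set
#'
#' Applies [normalized_rmsd()] to every unordered pair of a labeled model
#' set, returning a symmetric matrix with zero diagonal plus the matching
#' atom-count matrices.
#'
#' @param models named list of [structure_model()] objects.
#' @param region comparison region, as in [normalized_rmsd()].
#' @param aligned_pairs optional named list of per-pair correspondences,
#'   names `"label1|label2"`.
#' @return An object of class `rmsd_matrix`: `values` (normalized RMSD, A),
#'   `rmsd_align`, `atoms_total`, `atoms_aligned`, `labels`.
#' @export
pairwise_matrix <- function(models, region = c(11, 25),
                            aligned_pairs = NULL) {
  stopifnot(is.list(models), length(models) >= 2)
  labels <- names(models)
  if (is.null(labels) || any(labels == "")) {
    labels <- paste0("m", seq_along(models))
    names(models) <- labels
  }
  n <- length(models)
  V <- A <- Tn <- An <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pk <- paste0(labels[i], "|", labels[j])
      ap <- if (!is.null(aligned_pairs)) aligned_pairs[[pk]] else NULL
      r <- tryCatch(normalized_rmsd(models[[i]], models[[j]], ap, region),
                    error = function(e) {
                      stop("pair ", pk, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
      V[i, j] <- V[j, i] <- r$rmsd_norm
      A[i, j] <- A[j, i] <- r$rmsd_align
      Tn[i, j] <- Tn[j, i] <- sum(r$n_backbone)
      An[i, j] <- An[j, i] <- sum(r$n_aligned)
    }
  }
  structure(list(labels = labels, values = V, rmsd_align = A,
                 atoms_total = Tn, atoms_aligned = An, region = region),
            class = "rmsd_matrix")
}

#' Group structures by a normalized-RMSD closeness threshold
#'
#' Single-linkage grouping: models are connected whenever their normalized
#' RMSD is below the threshold, and connected components form the groups.
#' Each group's representative is the member with the smallest sum of
#' within-group distances (ties broken by label order), the natural choice
#' of a central exemplar when reducing many candidate models to a diverse
#' set.
#'
#' @param matrix an [pairwise_matrix()] result (or plain symmetric matrix).
#' @param threshold closeness threshold in A (default 3.5).
#' @return list with `groups` (list of label vectors), `representatives`
#'   and `membership` (named integer vector).
#' @export
group_structures <- function(matrix, threshold = 3.5) {
  V <- if (inherits(matrix, "rmsd_matrix")) matrix$values else as.matrix(matrix)
  labels <- rownames(V)
  if (is.null(labels)) labels <- paste0("m", seq_len(nrow(V)))
  adj <- (V < threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(labels, comp)
  names(groups) <- NULL
  # order groups by first-appearing member for determinism
  groups <- groups[order(vapply(groups, function(gr) match(gr[1], labels), 1L))]
  reps <- vapply(groups, function(gr) {
    idx <- match(gr, labels)
    sums <- rowSums(V[idx, idx, drop = FALSE])
    gr[which.min(sums)]  # which.min is first-match: ties go to label order
  }, character(1))
  membership <- stats::setNames(integer(length(labels)), labels)
  for (k in seq_along(groups)) membership[groups[[k]]] <- k
  list(groups = groups, representatives = reps, membership = membership,
       threshold = threshold)
}
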