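#' Substitution models and phylogenetic likelihoods
#'
#' Two time-reversible processes drive every likelihood in the package: an
#' HKY85 nucleotide model (base frequencies `pi`, transition/transversion
#' ratio `kappa`) used as the neutral reference, and an MG94xHKY codon model
#' over the 61 sense codons that layers a nonsynonymous/synonymous rate
#' ratio `omega` on top of the same nucleotide parameters. Likelihoods are
#' computed by Felsenstein pruning with per-column scaling; transition
#' probabilities come from the spectral decomposition of the symmetrized
#' rate matrix.
#'
#' @name models
NULL

# ---- codon bookkeeping -----------------------------------------------------

codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                                DNA_BASES, paste0))
      codons <- sort(codons)
      gc <- Biostrings::GENETIC_CODE[codons]
      sense <- codons[gc != "*"]
      tab <<- list(codons = codons, aa = gc, sense = sense,
                   sense_aa = gc[gc != "*"],
                   sense_index = setNames(seq_along(sense), sense))
    }
    tab
  }
})

encode_nuc <- function(chars) {
  match(chars, DNA_BASES)          # NA for gap/N/other = missing data
}

encode_codons <- function(codon_strings) {
  ct <- codon_table()
  unname(ct$sense_index[codon_strings])  # NA if not a sense codon
}

is_stop_codon <- function(codon_strings) {
  ct <- codon_table()
  aa <- ct$aa[codon_strings]
  !is.na(aa) & aa == "*"
}

# ---- rate matrices ---------------------------------------------------------

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# spectral decomposition of a reversible generator; returns closure pieces
decompose_generator <- function(Q, pi) {
  d <- sqrt(pi)
  B <- (d * Q) / rep(d, each = length(d))        # diag(d) Q diag(1/d), B sym
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors / d,                      # diag(1/d) V
       right = t(e$vectors * d))                  # t(V) diag(d)
}

#' Construct an HKY85 substitution model
#'
#' The generator is normalized to one expected substitution per site at
#' stationarity, so branch lengths are in substitutions/site.
#'
#' @param pi base frequencies, named or in A,C,G,T order; must be positive.
#' @param kappa transition/transversion rate ratio (> 0).
#' @return a `subst_model` of type `"nucleotide"`.
#' @export
hky_model <- function(pi = c(0.25, 0.25, 0.25, 0.25), kappa = 2) {
  pi <- as.numeric(pi)
  if (length(pi) != 4L || any(pi <= 0)) stop("pi must be 4 positive frequencies")
  pi <- pi / sum(pi)
  if (kappa <= 0) stop("kappa must be positive")
  names(pi) <- DNA_BASES
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (a in DNA_BASES) for (b in DNA_BASES) {
    if (a == b) next
    Q[a, b] <- pi[b] * if (is_transition(a, b)) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  structure(list(type = "nucleotide", states = DNA_BASES, pi = pi,
                 kappa = kappa, Q = Q, eig = decompose_generator(Q, pi)),
            class = "subst_model")
}

#' Construct an MG94xHKY codon model
#'
#' Single-nucleotide codon substitutions occur at rate proportional to the
#' target-nucleotide frequency, multiplied by `kappa` for transitions and
#' `omega` for nonsynonymous changes; stop codons are excluded (61 sense
#' states). Normalized to one expected substitution per codon, so a codon
#' branch length of `3t` matches a nucleotide branch length `t` under
#' neutrality.
#'
#' @param pi nucleotide frequencies shared with the neutral model.
#' @param kappa transition/transversion ratio shared with the neutral model.
#' @param omega nonsynonymous/synonymous rate ratio (> 0).
#' @return a `subst_model` of type `"codon"` with 61 states.
#' @export
mg94_model <- function(pi = c(0.25, 0.25, 0.25, 0.25), kappa = 2,
                       omega = 0.2) {
  pi <- as.numeric(pi); pi <- pi / sum(pi); names(pi) <- DNA_BASES
  if (omega <= 0) stop("omega must be positive")
  ct <- codon_table()
  sense <- ct$sense
  n <- length(sense)
  aa <- ct$sense_aa
  pos <- lapply(1:3, function(p) substr(sense, p, p))
  Q <- matrix(0, n, n, dimnames = list(sense, sense))
  for (p in 1:3) {
    for (i in seq_len(n)) {
      same_other <- rep(TRUE, n)
      for (q in setdiff(1:3, p)) same_other <- same_other & pos[[q]] == pos[[q]][i]
      js <- which(same_other & pos[[p]] != pos[[p]][i])
      for (j in js) {
        r <- pi[pos[[p]][j]]
        if (is_transition(pos[[p]][i], pos[[p]][j])) r <- r * kappa
        if (aa[i] != aa[j]) r <- r * omega
        Q[i, j] <- r
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  pic <- pi[pos[[1]]] * pi[pos[[2]]] * pi[pos[[3]]]
  pic <- pic / sum(pic)
  names(pic) <- sense
  mu <- -sum(pic * diag(Q))
  Q <- Q / mu
  structure(list(type = "codon", states = sense, pi = pic, pi_nuc = pi,
                 kappa = kappa, omega = omega, Q = Q,
                 eig = decompose_generator(Q, pic)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("<subst_model> %s, %d states, kappa=%.3g%s\n", x$type,
              length(x$states), x$kappa,
              if (!is.null(x$omega)) sprintf(", omega=%.3g", x$omega) else ""))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a `subst_model`.
#' @param t branch length (>= 0).
#' @return stochastic matrix over the model's states.
#' @export
prob_matrix <- function(model, t) {
  if (t < 0) stop("branch length must be non-negative")
  e <- model$eig
  P <- e$left %*% (exp(e$values * t) * e$right)
  P[P < 0] <- 0
  P / rowSums(P)
}

# ---- tree plumbing ---------------------------------------------------------

# postorder edge traversal info for a rooted ape tree
tree_info <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  list(tree = tree, edge = tree$edge, lengths = tree$edge.length,
       ntip = length(tree$tip.label), tips = tree$tip.label,
       nnode = tree$Nnode, root = length(tree$tip.label) + 1L)
}

#' Felsenstein pruning log-likelihood
#'
#' Computes per-column log-likelihoods of tip states under a substitution
#' model on a rooted tree, by postorder accumulation of partial likelihoods
#' with per-column rescaling. Missing tip states (NA) contribute a partial
#' vector of ones (standard missing-data treatment, which also covers `N`
#' and alignment gaps).
#'
#' @param model a `subst_model`.
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param tip_states integer matrix, rows = tree tip labels (rownames
#'   required unless in tip order), columns = alignment columns; entries are
#'   state indices or NA.
#' @param rate_scale multiplier applied to every branch length.
#' @return list with `total` (log-likelihood) and `per_column` vector.
#' @export
prune_loglik <- function(model, tree, tip_states, rate_scale = 1) {
  if (rate_scale < 0) stop("rate_scale must be non-negative")
  ti <- tree_info(tree)
  S <- length(model$states)
  if (!is.null(rownames(tip_states))) {
    miss <- setdiff(ti$tips, rownames(tip_states))
    if (length(miss)) stop("tip_states missing rows for: ",
                           paste(miss, collapse = ", "))
    tip_states <- tip_states[ti$tips, , drop = FALSE]
  } else if (nrow(tip_states) != ti$ntip) {
    stop("tip_states must have one row per tree tip")
  }
  C <- ncol(tip_states)
  if (C == 0L) stop("no usable alignment columns")
  nnode_total <- ti$ntip + ti$nnode
  partial <- vector("list", nnode_total)
  logscale <- numeric(C)
  Pcache <- lapply(ti$lengths, function(b) prob_matrix(model, b * rate_scale))
  for (i in seq_len(ti$ntip)) {
    L <- matrix(0, S, C)
    st <- tip_states[i, ]
    ok <- !is.na(st)
    if (any(ok)) L[cbind(st[ok], which(ok))] <- 1
    if (any(!ok)) L[, !ok] <- 1
    partial[[i]] <- L
  }
  done <- logical(nnode_total)
  for (k in seq_len(nrow(ti$edge))) {
    parent <- ti$edge[k, 1L]; child <- ti$edge[k, 2L]
    contrib <- Pcache[[k]] %*% partial[[child]]
    if (!done[parent]) {
      partial[[parent]] <- contrib
      done[parent] <- TRUE
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
    }
    # rescale to avoid underflow
    mx <- apply(partial[[parent]], 2L, max)
    mx[mx == 0] <- 1
    partial[[parent]] <- sweep(partial[[parent]], 2L, mx, "/")
    logscale <- logscale + log(mx)
  }
  root_like <- as.numeric(model$pi %*% partial[[ti$root]])
  per_column <- log(root_like) + logscale
  list(total = sum(per_column), per_column = per_column)
}

# ---- state simulation ------------------------------------------------------

#' Simulate tip states down a tree
#'
#' Samples a root sequence from the model's stationary distribution and
#' evolves it along each edge using exact transition probabilities
#' (matrix exponentials, no discretization).
#'
#' @param model a `subst_model`.
#' @param tree rooted `ape::phylo`.
#' @param n_sites number of independent columns.
#' @param rate_scale branch-length multiplier.
#' @param root_states optional integer vector of length `n_sites` to use as
#'   the root sequence instead of sampling.
#' @return list with `tips` (integer matrix, rownames = tip labels) and
#'   `root` (integer vector). Uses the current RNG stream.
#' @export
simulate_states <- function(model, tree, n_sites, rate_scale = 1,
                            root_states = NULL) {
  ti <- tree_info(tree)
  S <- length(model$states)
  if (is.null(root_states)) {
    root_states <- sample.int(S, n_sites, replace = TRUE, prob = model$pi)
  }
  nnode_total <- ti$ntip + ti$nnode
  states <- vector("list", nnode_total)
  states[[ti$root]] <- root_states
  # preorder = reverse postorder edge list
  for (k in rev(seq_len(nrow(ti$edge)))) {
    parent <- ti$edge[k, 1L]; child <- ti$edge[k, 2L]
    P <- prob_matrix(model, ti$lengths[k] * rate_scale)
    ps <- states[[parent]]
    out <- integer(n_sites)
    for (s in seq_len(S)) {
      idx <- which(ps == s)
      if (length(idx)) {
        out[idx] <- sample.int(S, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    states[[child]] <- out
  }
  tips <- do.call(rbind, states[seq_len(ti$ntip)])
  rownames(tips) <- ti$tips
  list(tips = tips, root = root_states)
}
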