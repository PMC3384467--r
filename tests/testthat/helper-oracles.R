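# shared fixtures and independent oracles used across test files

# small reference panel: 4 taxa per clade category (20 taxa)
small_panel <- function(n = 4L) {
  simulate_taxonomy(c(PROTEO = n, OTHER_BACT = n, THERMO_ARCH = n,
                      HALO_ARCH = n, OTHER_ARCH = n), seed = 1L)
}

# 20-state equal-exchangeability, uniform-frequency model (Jukes-Cantor
# analogue); its ML distance has the closed form -(19/20) log(1 - 20p/19)
equal_rates_model <- function() {
  s <- matrix(1, 20L, 20L)
  subst_model(s, rep(1 / 20, 20L))
}

# brute-force union length of 1-based inclusive intervals via a base mask
mask_union_length <- function(starts, ends, total) {
  mask <- logical(total)
  for (k in seq_along(starts)) mask[starts[k]:ends[k]] <- TRUE
  sum(mask)
}

# exhaustive 4-leaf log-likelihood: sum over both internal node states.
# Tree shape ((a,b)n, c, d)r with the five branch lengths given.
exhaustive_quartet_loglik <- function(model, lens, states_abcd) {
  P1 <- prob_matrix(model, lens[1]); P2 <- prob_matrix(model, lens[2])
  P3 <- prob_matrix(model, lens[3]); P4 <- prob_matrix(model, lens[4])
  P5 <- prob_matrix(model, lens[5])
  tot <- 0
  for (col in seq_len(ncol(states_abcd))) {
    st <- states_abcd[, col]
    l <- 0
    for (x in 1:20) for (y in 1:20) {
      l <- l + model$pi[x] * P5[x, y] * P1[y, st[1]] * P2[y, st[2]] *
        P3[x, st[3]] * P4[x, st[4]]
    }
    tot <- tot + log(l)
  }
  tot
}

# the matching unrooted quartet as a phylo object
quartet_tree <- function(lens, labels = c("a", "b", "c", "d")) {
  txt <- sprintf("((%s:%.17g,%s:%.17g):%.17g,%s:%.17g,%s:%.17g);",
                 labels[1], lens[1], labels[2], lens[2], lens[5],
                 labels[3], lens[3], labels[4], lens[4])
  ape::read.tree(text = txt)
}

# alignment from an integer state matrix (rows = taxa)
aln_from_states <- function(states, ids, cog_id = "TEST") {
  mat <- matrix(AMINO_ACIDS[states], nrow = nrow(states),
                dimnames = list(ids, NULL))
  cog_alignment(cog_id, mat)
}

# exhaustive exploration of every order of Z-rule applications on a tiny
# split set; returns the set of reachable fixpoint states (each a sorted
# character vector of canonical split keys)
closure_fixpoints <- function(ss, max_states = 5000L) {
  key_state <- function(splits)
    paste(sort(vapply(splits, cogevo:::split_key, "")), collapse = " ")
  apply_all <- function(splits) {
    nexts <- list()
    n <- length(splits)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (o1 in cogevo:::orientations(splits[[i]]))
        for (o2 in cogevo:::orientations(splits[[j]])) {
          r <- cogevo:::z_rule(o1, o2)
          if (!is.null(r)) {
            s2 <- splits
            s2[[i]] <- r$s1; s2[[j]] <- r$s2
            s2 <- split_set(ss$universe, s2)$splits
            nexts <- c(nexts, list(s2))
          }
        }
    }
    nexts
  }
  seen <- character(0)
  fixpoints <- list()
  queue <- list(ss$splits)
  while (length(queue)) {
    splits <- queue[[1L]]; queue <- queue[-1L]
    k <- key_state(splits)
    if (k %in% seen) next
    seen <- c(seen, k)
    if (length(seen) > max_states) stop("closure state space too large")
    nxt <- apply_all(splits)
    if (!length(nxt)) {
      fixpoints[[k]] <- sort(vapply(splits, cogevo:::split_key, ""))
    } else {
      queue <- c(queue, nxt)
    }
  }
  fixpoints
}

split_keys <- function(ss) sort(vapply(ss$splits, cogevo:::split_key, ""))

# unrooted topology equality through ape
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}
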