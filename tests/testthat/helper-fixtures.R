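# shared fixtures and independent oracles, built in code at test time

# two haploid populations split at tau over an ancestral pop of size theta
two_pop_config <- function(tau = 0.002, theta_anc = 0.01,
                           theta_leaf = 1e-8) {
  demography_config(
    populations = data.frame(name = c("A", "B", "AB"),
                             theta = c(theta_leaf, theta_leaf, theta_anc)),
    splits = data.frame(parent = "AB", child1 = "A", child2 = "B",
                        time = tau),
    samples = data.frame(sample = c("a", "b"), population = c("A", "B"),
                         age = 0, ploidy = 1))
}

# exact probability two haploid lineages differ at a site: odd number of
# Poisson mutations over length 2*tau + 2*T, T ~ Exp(2/theta)
two_pop_diff_prob <- function(tau, theta) {
  (1 - exp(-4 * tau) / (1 + 2 * theta)) / 2
}

# four-lineage dating world matching the analytic expectation's model;
# haploid singletons, optionally with diploid modern panels
dating_config <- function(tau1 = 0.0015, P2 = 0.002, P3 = 0.003,
                          alpha = 0.2, theta = 0.01)
  study_demography(tau1 = tau1, P2 = P2, P3 = P3, alpha = alpha,
                   theta = theta)

# hand-rolled per-read likelihood oracle, independent of site_likelihoods:
# straight product over reads of the damage-then-error composition
oracle_loglik <- function(reads, damage, genotype, cap_bq = 40) {
  nts <- c("A", "C", "G", "T")
  p_obs_allele <- function(obs, allele, strand, pos5, pos3, eps) {
    if (strand == "+") {
      dct <- damage_probability(damage, "5prime", pos5)
      dga <- damage_probability(damage, "3prime", pos3)
    } else {
      dga <- damage_probability(damage, "5prime", pos5)
      dct <- damage_probability(damage, "3prime", pos3)
    }
    p_dam <- setNames(as.numeric(nts == allele), nts)
    if (allele == "C") { p_dam["C"] <- 1 - dct; p_dam["T"] <- dct }
    if (allele == "G") { p_dam["G"] <- 1 - dga; p_dam["A"] <- dga }
    sum(vapply(nts, function(b)
      (if (obs == b) 1 - eps else eps / 3) * p_dam[[b]], 0))
  }
  a1 <- substr(genotype, 1, 1); a2 <- substr(genotype, 2, 2)
  ll <- 0
  for (i in seq_len(nrow(reads))) {
    eps <- 10^(-min(reads$qual[i], cap_bq) / 10)
    p1 <- p_obs_allele(reads$base[i], a1, reads$strand[i],
                       reads$pos5[i], reads$pos3[i], eps)
    p2 <- p_obs_allele(reads$base[i], a2, reads$strand[i],
                       reads$pos5[i], reads$pos3[i], eps)
    ll <- ll + log((p1 + p2) / 2)
  }
  ll
}

make_reads <- function(base, n, qual = 30, mapq = 37, strand = "+",
                       pos5 = 25, pos3 = 25, len = 70) {
  data.frame(base = rep(base, n), qual = qual, mapq = mapq,
             strand = strand, pos5 = pos5, pos3 = pos3, len = len,
             stringsAsFactors = FALSE)
}

# Gaussian-drift allele-frequency simulator on a tree/graph: an
# independent oracle for f-statistics (drift lengths are in f2 units)
drift_child <- function(p, len) {
  pmin(pmax(p + rnorm(length(p), 0, sqrt(len * p * (1 - p))), 0), 1)
}

# panel with two clean clades (AB vs CD) for tree tests
two_clade_panel <- function(n_sites = 2000, n_blocks = 20, seed = 42,
                            sep = 0.3) {
  set.seed(seed)
  p0 <- runif(n_sites, 0.2, 0.8)
  pab <- drift_child(p0, sep)
  pcd <- drift_child(p0, sep)
  g <- cbind(A = rbinom(n_sites, 2, drift_child(pab, 0.01)),
             B = rbinom(n_sites, 2, drift_child(pab, 0.01)),
             C = rbinom(n_sites, 2, drift_child(pcd, 0.01)),
             D = rbinom(n_sites, 2, drift_child(pcd, 0.01)))
  genotype_panel(g, block_id = rep(seq_len(n_blocks),
                                   each = n_sites / n_blocks))
}

# enumeration oracle for expected f4 on an admixture graph: averages the
# plain tree f4 over all (independent) routings of the four lineage slots
enumerate_f4 <- function(graph, pops) {
  adm <- graph$admix
  n_adm <- if (is.null(adm)) 0 else nrow(adm)
  routings <- expand.grid(rep(list(c(TRUE, FALSE)), n_adm * 4))
  tree_usage <- function(choice_for_slot) {
    # route one lineage slot: admixture child k takes parent1 iff choice[k]
    function(leaf, choices) {
      mass <- setNames(numeric(length(graph$nodes)), graph$nodes)
      mass[leaf] <- 1
      u <- numeric(nrow(graph$edges))
      node <- leaf
      while (node != graph$root) {
        k <- if (n_adm) which(adm$child == node) else integer(0)
        if (length(k)) {
          node <- if (choices[k]) adm$parent1[k] else adm$parent2[k]
        } else {
          ei <- which(graph$edges$to == node)
          u[ei] <- 1
          node <- graph$edges$from[ei]
        }
      }
      u
    }
  }
  route <- tree_usage(NULL)
  total <- 0
  for (r in seq_len(max(1, nrow(routings)))) {
    ch <- if (n_adm) matrix(unlist(routings[r, ]), nrow = 4) else
      matrix(logical(0), nrow = 4)
    pr <- 1
    for (slot in 1:4) for (k in seq_len(n_adm))
      pr <- pr * if (ch[slot, k]) adm$prop[k] else 1 - adm$prop[k]
    us <- lapply(1:4, function(slot)
      route(pops[slot], if (n_adm) ch[slot, ] else logical(0)))
    val <- sum(graph$edges$length * (us[[1]] - us[[2]]) *
                 (us[[3]] - us[[4]]))
    total <- total + pr * val
  }
  total
}
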