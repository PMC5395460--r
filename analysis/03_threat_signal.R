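#!/usr/bin/env Rscript
# Phylogenetic pattern of extinction risk: is threat status (threatened =
# VU/EN/CR vs not) clustered on the tree (Fritz-Purvis D), and are
# threatened species more evolutionarily distinct (one-way ANOVA of ED)?

library(cycadrisk)
library(jsonlite)

tree <- read_newick("results/data/tree.nwk")
threats <- read_threats("results/data/threats.tsv")

trait <- threat_trait(threats)
sig_tree <- if (length(trait) < ape::Ntip(tree))
  prune_to(tree, names(trait)) else tree
dstat <- d_statistic(sig_tree, trait, n_perm = 1000, n_sim = 1000,
                     seed = 2026L)
print(dstat)
write_json(unclass(dstat), "results/d_statistic.json", auto_unbox = TRUE,
           digits = NA, pretty = TRUE)

ed <- fair_proportion_ed(tree)
grp2 <- stats::setNames(ifelse(trait == 1, "threatened", "nonthreatened"),
                        names(trait))
a2 <- ed_group_test(ed, grp2)
cat(sprintf("\nED ~ threatened/nonthreatened: F = %.3f, p = %.4f\n",
            a2$F, a2$p))
cat(sprintf("  group means (Myr): %s\n",
            paste(names(a2$means), round(a2$means, 2), sep = "=",
                  collapse = ", ")))

grp5 <- stats::setNames(threats$category, threats$species)
grp5 <- grp5[grp5 != "DD"]
a5 <- ed_group_test(ed, grp5)
cat(sprintf("ED ~ IUCN category (%s): F = %.3f, p = %.4f\n",
            paste(names(a5$means), collapse = "/"), a5$F, a5$p))
write_json(list(threatened_vs_not = list(F = a2$F, p = a2$p,
                                         means = as.list(a2$means)),
                by_category = list(F = a5$F, p = a5$p,
                                   means = as.list(a5$means))),
           "results/ed_anova.json", auto_unbox = TRUE, digits = NA,
           pretty = TRUE)
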