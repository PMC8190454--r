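#!/usr/bin/env Rscript

# Regime maps over parameter space: which form of resistance (chromosomal,
# plasmid-borne, either, or none) is evolutionarily stable. Reproduces the
# two main regime diagrams — antibiotic pressure x resistance cost, and
# plasmid transmission x plasmid cost — at a desk-scale 41 x 41 resolution.
#
# Finding (at the reference parameterisation): the A x cR plane is dominated
# by bistability, with chromosomal-only resistance confined to a narrow band
# of very cheap resistance genes (cR below about 0.01), plasmid-only
# resistance to a small pocket of weakly beneficial genes at low A, and
# no-resistance to very low antibiotic pressure. The beta x cP plane splits
# cleanly: plasmid-involving regimes require transmission above a threshold
# that rises with the plasmid's cost.

library(plasmidfate)

dir.create("results", showWarnings = FALSE)
n <- 41

message("A x cR sweep (", n, " x ", n, ") ...")
left <- run_scenario("fig2_left", out_dir = "results", grid = n)
print(table(left$table$regime))

message("beta x cP sweep (", n, " x ", n, ") ...")
right <- run_scenario("fig2_right", out_dir = "results", grid = n)
print(table(right$table$regime))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  pal <- c(bistable = "#8c6bb1", chromosomal_only = "#e08214",
           plasmid_only = "#4393c3", no_resistance = "grey90")
  g1 <- ggplot(left$table, aes(A, cR, fill = regime)) +
    geom_tile() + scale_fill_manual(values = pal) +
    labs(title = "Evolutionary stability of resistance location",
         x = "antibiotic-associated death rate A",
         y = "cost of resistance cR") + theme_minimal()
  g2 <- ggplot(right$table, aes(beta, cP, fill = regime)) +
    geom_tile() + scale_fill_manual(values = pal) +
    labs(x = "plasmid transmission rate beta", y = "cost of plasmid cP") +
    theme_minimal()
  ggsave("results/fig2_regimes.pdf", g1, width = 6, height = 4)
  ggsave("results/fig2_regimes_beta_cP.pdf", g2, width = 6, height = 4)
  message("wrote results/fig2_regimes*.pdf")
}
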