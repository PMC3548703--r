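# Frozen operating points for the knowledge base's suggested parameters.
# Every value here was fixed once by the committed calibration sweep
# (scripts/calibration.R) against the packaged DIP yeast subnetwork and is
# not meant to be tuned per run; the sweep's reasoning is laid out in the
# methods vignette.

# Defective-clique completion: smallest common-clique size that reduces the
# candidate set to the best-supported near-cliques (4-clique support), and a
# cap of one completion per run, the knowledge base's "considerable value".
DEFAULT_MIN_COMMON <- 4L
DEFAULT_MAX_PREDICTIONS <- 1L

# Betweenness-centrality false-positive filter: rank-based removal of the
# top-k highest-betweenness edges.
DEFAULT_BC_TOP_K <- 3L

# Estimated false-positive rate of high-throughput interaction screens:
# roughly half of reported interactions may be spurious. Networks whose
# curated-core fraction exceeds this rate are treated as addition-first
# (false-negative completion) rather than deletion-first.
HIGH_THROUGHPUT_FP_RATE <- 0.5

# MCL defaults for S. cerevisiae PPI networks.
DEFAULT_MCL_INFLATION_YEAST <- 2.2

# MCODE defaults: vertex weight percentage, haircut on, fluff off.
DEFAULT_MCODE_VWP <- 0.2

# RNSC defaults.
DEFAULT_RNSC_RESTARTS <- 50L
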