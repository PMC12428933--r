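# Synthetic data: toy networks, the reconstructed CLL/RS model, and
# sparse expression matrices with ground truth ------------------------------

#' Uniformly random network state
#'
#' @param n number of nodes.
#' @param seed optional integer seed.
#' @return 0/1 integer vector of length `n`.
#' @export
random_state <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(0:1, n, replace = TRUE)
}

#' Named toy networks with known attractor landscapes
#'
#' Each fixture carries its network and its exhaustively enumerated ground
#' truth landscape:
#' * `swap`: A' = B, B' = A (two fixed points and one 2-cycle, basins
#'   1/1/2),
#' * `identity3`: three self-copying nodes (`2^3` fixed points, basin 1
#'   each),
#' * `constant`: functions fixed to 1/0/1 (single fixed point, basin
#'   `2^3`),
#' * `repressor`: T' = !R, R' = R,
#' * `andgate`: C' = A & B with self-copying inputs.
#'
#' @return named list; each element has `network` and `landscape`.
#' @export
toy_networks <- function() {
  nets <- list(
    swap = boolean_network(c(A = "B", B = "A")),
    identity3 = boolean_network(c(A = "A", B = "B", C = "C")),
    constant = boolean_network(c(A = "1", B = "0", C = "1")),
    repressor = boolean_network(c(R = "R", T = "!R")),
    andgate = boolean_network(c(A = "A", B = "B", C = "A & B"))
  )
  lapply(nets, function(n) list(network = n,
                                landscape = exhaustive_attractors(n)))
}

# Rules of the reconstructed CLL/RS network.  Every regulation is motivated
# by the literature-described circuits of the CLL-to-Richter system (see the
# provenance table); where the sources are silent, minimal pass-through
# logic is used and flagged as such.  This is a best-effort reconstruction,
# not the authoritative published rule set: basin percentages are not
# comparable, only qualitative attractor behavior.
.cll_rules <- function() {
  c(
    BCR    = "BCR",
    TME    = "TME",
    LYN    = "BCR",
    SHP1   = "LYN & (NFAT | SHP1)",
    SYK    = "BCR & !SHP1",
    ZAP70  = "BCR & !SHP1",
    BTK    = "SYK | ZAP70",
    PLCG2  = "BTK",
    STIM1  = "LYN | PLCG2",
    PKCB   = "STIM1",
    GSK3B  = "!PKCB & !AKT",
    NFAT   = "STIM1 & !GSK3B & !NOTCH1",
    ERK    = "PKCB",
    PI3K   = "SYK | ZAP70 | TME",
    PTEN   = "NFAT",
    AKT    = "PI3K & !PTEN & !PP2A",
    NOTCH1 = "AKT",
    S100A4 = "!NFAT",
    MDM2   = "AKT",
    TP53   = "!MDM2 & !S100A4",
    MYC    = "(ERK | NOTCH1) & !TP53",
    SET    = "MYC | GSK3B | LYN",
    PP2A   = "!SET",
    CITED2 = "MYC & !NOTCH1",
    BMI1   = "(CITED2 | MYC) & AKT",
    NFKB   = "(BTK & PKCB) | (TME & AKT)",
    BCL2   = "NFKB",
    BIM    = "!ERK & !BCL2",
    CD5    = "NFAT",
    CDKN1A = "TP53 & !MYC",
    CDKN2A = "(TP53 | NFAT) & !BMI1",
    CDKN2B = "(TP53 | NFAT) & !BMI1",
    CDKN1B = "!AKT & !MYC",
    CCND1  = "(ERK | MYC | NOTCH1) & !CDKN2A & !CDKN2B",
    E2F    = "CCND1",
    CCNE1  = "E2F & !CDKN1A & !CDKN1B",
    SPhase = "E2F & CCNE1",
    Apoptosis = "BIM & !AKT",
    Anergy = "NFAT & !NFKB & !AKT & !SPhase"
  )
}

.cll_provenance <- function() {
  c(
    BCR    = "input: B-cell receptor stimulation (self-copying input node)",
    TME    = "input: microenvironmental costimulation (self-copying input node)",
    LYN    = "proximal BCR kinase, active under receptor engagement",
    SHP1   = "inhibitory phosphatase; sustained by LYN and latched by the NFAT anergy program",
    SYK    = "BCR-proximal kinase, silenced by SHP1 in anergic cells",
    ZAP70  = "SYK-family kinase expressed in aggressive CLL; silenced by SHP1 (minimal pass-through)",
    BTK    = "downstream of SYK/ZAP70 signalosome",
    PLCG2  = "activated downstream of BTK",
    STIM1  = "store-operated calcium signaling sustained by LYN/PLCG2",
    PKCB   = "calcium/DAG-dependent kinase downstream of the Ca signal; first step of the anergic circuit",
    GSK3B  = "receives inhibitory phosphorylation from PKC and AKT",
    NFAT   = "calcium-dependent; nuclear when GSK3B is inhibited; shut off by NOTCH1",
    ERK    = "MAPK arm downstream of PKC, active in anergic CLL",
    PI3K   = "activated by SYK/ZAP70 and by TME costimulation",
    PTEN   = "lipid phosphatase, expression promoted by NFAT",
    AKT    = "requires PI3K, antagonized by PTEN and by PP2A",
    NOTCH1 = "activated upon AKT hyperactivation (minimal pass-through)",
    S100A4 = "expressed upon NFAT loss",
    MDM2   = "E3 ligase stabilized by AKT",
    TP53   = "degraded redundantly via MDM2 and S100A4",
    MYC    = "transcription repressed by TP53; induced via ERK/NOTCH1",
    SET    = "expression activated by GSK3B and LYN, weakly by MYC",
    PP2A   = "phosphatase inhibited by SET complexes",
    CITED2 = "transcriptional MYC target, counteracted by NOTCH1",
    BMI1   = "stabilized by MYC/CITED2 together with AKT activity",
    NFKB   = "canonical BCR arm (BTK+PKC) or TME costimulation through AKT",
    BCL2   = "anti-apoptotic NF-kB target",
    BIM    = "pro-apoptotic; suppressed by ERK signaling and sequestered by BCL2",
    CD5    = "anergy marker, expression promoted by NFAT",
    CDKN1A = "p21: TP53 target strongly repressed by MYC",
    CDKN2A = "INK4/ARF locus sustained by TP53/NFAT, repressed by BMI1",
    CDKN2B = "INK4b sustained by TP53/NFAT, repressed by BMI1",
    CDKN1B = "p27: lost under AKT and MYC activity",
    CCND1  = "cyclin D: mitogenic induction, blocked by INK4 inhibitors",
    E2F    = "released downstream of cyclin D activity (Rb implicit)",
    CCNE1  = "cyclin E: E2F target, blocked by CIP/KIP inhibitors",
    SPhase = "indicator: S-phase entry = E2F and cyclin E jointly active",
    Apoptosis = "indicator: BIM active with inactive AKT",
    Anergy = "indicator: NFAT active with NF-kB, AKT and S phase inactive"
  )
}

#' The reconstructed CLL/RS Boolean network
#'
#' A 39-node reconstruction of the CLL signaling network covering the BCR
#' signalosome, the NFAT anergy program, the PI3K/AKT axis, the
#' TP53/MDM2/S100A4 module, MYC and its targets (CITED2, BMI1), the
#' CDKN1A/2A/2B/1B cell-cycle inhibitors, the cyclin D/E - E2F axis and the
#' three phenotype indicator nodes (S phase, apoptosis, anergy).  Rules are
#' reconstructed from described regulatory circuits; the card records a
#' per-rule provenance note.  Basin percentages of this reconstruction are
#' not asserted against any published value — only the qualitative behavior
#' exercised by [cll_scenarios()] is.
#'
#' @return a `reconstructed_model_card`: list with `network`
#'   (`boolean_network`), `provenance` (named character), and `indicators`.
#' @export
reconstructed_cll_network <- function() {
  structure(list(network = boolean_network(.cll_rules()),
                 provenance = .cll_provenance(),
                 indicators = cll_indicators()),
            class = "reconstructed_model_card")
}

#' @export
print.reconstructed_model_card <- function(x, ...) {
  cat("Reconstructed CLL/RS Boolean model:", length(x$network$nodes),
      "nodes (literature-motivated reconstruction)\n")
  invisible(x)
}

#' Named simulation scenarios of the CLL/RS model
#'
#' Every scenario is an [intervention()] on the reconstructed model.  The
#' CLL conditions keep BCR stimulation on (`BCR = 1`) without
#' microenvironmental costimulation (`TME = 0`) unless stated otherwise:
#' * `cll`: unperturbed CLL under BCR stimulation,
#' * `igm_ko`: withdrawal of IgM/BCR stimulation,
#' * `igm_ko_bcl2_ki`: IgM withdrawal with constitutive BCL2,
#' * `cdkn2ab_ko`: CDKN2A/B loss with wild-type TP53,
#' * `rs_cdkn2ab_tp53_ko`: CDKN2A/B plus TP53 loss (RS condition),
#' * `rs_cdkn2ab_tp53_bcr_ko`: the same plus BCR withdrawal,
#' * `rs_akt_ki`: constitutive AKT (RS condition),
#' * `rs_notch1_ki`: constitutive NOTCH1 (RS condition),
#' * `rs_nfat_ko`: NFAT loss (RS condition),
#' * `tme`: unperturbed CLL with microenvironmental costimulation,
#' * `high_risk`: MYC and ZAP70 knockin with TP53 knockout,
#' * `bmi1_ki`, `tp53_ko`, `bmi1_ki_tp53_ko`: the two-hit driver study.
#'
#' @return named list of interventions.
#' @export
cll_scenarios <- function() {
  cll <- c(BCR = 1, TME = 0)
  list(
    cll = intervention(values = cll),
    igm_ko = intervention(values = c(BCR = 0, TME = 0)),
    igm_ko_bcl2_ki = intervention(values = c(BCR = 0, TME = 0, BCL2 = 1)),
    cdkn2ab_ko = intervention(values = c(cll, CDKN2A = 0, CDKN2B = 0)),
    rs_cdkn2ab_tp53_ko = intervention(values = c(cll, CDKN2A = 0, CDKN2B = 0,
                                                 TP53 = 0)),
    rs_cdkn2ab_tp53_bcr_ko = intervention(values = c(BCR = 0, TME = 0,
                                                     CDKN2A = 0, CDKN2B = 0,
                                                     TP53 = 0)),
    rs_akt_ki = intervention(values = c(cll, AKT = 1)),
    rs_notch1_ki = intervention(values = c(cll, NOTCH1 = 1)),
    rs_nfat_ko = intervention(values = c(cll, NFAT = 0)),
    tme = intervention(values = c(BCR = 1, TME = 1)),
    high_risk = intervention(values = c(cll, MYC = 1, ZAP70 = 1, TP53 = 0)),
    bmi1_ki = intervention(values = c(cll, BMI1 = 1)),
    tp53_ko = intervention(values = c(cll, TP53 = 0)),
    bmi1_ki_tp53_ko = intervention(values = c(cll, BMI1 = 1, TP53 = 0))
  )
}

#' Simulate a named scenario of the reconstructed CLL model
#'
#' Convenience wrapper: applies the scenario intervention and estimates the
#' attractor landscape.
#'
#' @param scenario scenario name, see [cll_scenarios()].
#' @param n_samples random starts for basin estimation.
#' @param seed optional integer seed.
#' @param card optionally a pre-built [reconstructed_cll_network()].
#' @return an `attractor_landscape`.
#' @export
simulate_cll_scenario <- function(scenario, n_samples = 100000L, seed = NULL,
                                  card = reconstructed_cll_network()) {
  sc <- cll_scenarios()
  if (!scenario %in% names(sc))
    stop("unknown scenario; available: ", paste(names(sc), collapse = ", "))
  net <- apply_interventions(card$network, sc[[scenario]])
  sampled_attractors(net, n_samples, seed = seed)
}

#' Synthetic sparse expression matrix with ground truth
#'
#' Per gene, each cell is assigned to a low or high log-normal expression
#' mode (mixing fraction `pi_high`), and the observed value is zeroed with
#' probability `dropout`.  `n_flat` genes are all-zero (to exercise the
#' exclusion path), and the five cyclin signature genes are planted with
#' their own mixing fractions so proliferative-cell selection has a known
#' outcome.  Ground truth is the mode membership; dropout cells retain
#' their mode label, and the dropout mask is returned so recovery can be
#' judged on observed entries.
#'
#' @param n_genes total number of genes (including flat and cyclin genes).
#' @param n_cells number of cells.
#' @param mu_lo,mu_hi log-scale means of the low/high modes.
#' @param sigma log-scale standard deviation (separation =
#'   `(mu_hi - mu_lo) / sigma`, 4 by default).
#' @param pi_high probability of the high mode; scalar or per-gene vector
#'   (recycled over non-cyclin, non-flat genes).
#' @param dropout probability that an observed value is zeroed.
#' @param n_flat number of all-zero genes.
#' @param cyclin_genes names of the planted cyclin signature genes.
#' @param cyclin_pi per-cyclin high-mode probability (recycled).
#' @param planted optional named numeric vector: additional genes planted
#'   under their own names with the given high-mode probabilities (e.g.
#'   marker genes of a node-gene map with known activation status).
#' @param seed optional integer seed.
#' @return list with `matrix` (genes x cells), `truth` (0/1 mode
#'   membership), `dropped` (logical mask), `flat_genes`, and the
#'   parameters in `spec`.
#' @export
synth_expression <- function(n_genes = 200L, n_cells = 500L,
                             mu_lo = 0, mu_hi = 2, sigma = 0.5,
                             pi_high = 0.5, dropout = 0.3, n_flat = 10L,
                             cyclin_genes = c("CCNE1", "CCNE2", "CCND1",
                                              "CCND2", "CCND3"),
                             cyclin_pi = 0.6, planted = NULL, seed = NULL) {
  if (mu_lo >= mu_hi) stop("mu_lo must be smaller than mu_hi")
  if (dropout < 0 || dropout > 1) stop("dropout must be in [0, 1]")
  if (any(pi_high < 0 | pi_high > 1)) stop("pi_high must be in [0, 1]")
  n_cyc <- length(cyclin_genes)
  n_pl <- length(planted)
  if (n_pl && (is.null(names(planted)) || any(!nzchar(names(planted)))))
    stop("planted genes must be named")
  if (n_genes < n_flat + n_cyc + n_pl + 1L)
    stop("n_genes too small for the requested flat, cyclin and planted genes")
  if (!is.null(seed)) set.seed(seed)
  n_reg <- n_genes - n_flat - n_cyc - n_pl
  genes <- c(cyclin_genes, names(planted),
             sprintf("G%03d", seq_len(n_reg)),
             if (n_flat > 0L) sprintf("FLAT%02d", seq_len(n_flat)))
  if (anyDuplicated(genes)) stop("duplicated gene names in the layout")
  pi_gene <- c(rep_len(cyclin_pi, n_cyc), as.numeric(planted),
               rep_len(pi_high, n_reg), rep(0, n_flat))
  truth <- matrix(0L, n_genes, n_cells,
                  dimnames = list(genes, sprintf("C%04d", seq_len(n_cells))))
  vals <- matrix(0, n_genes, n_cells, dimnames = dimnames(truth))
  dropped <- matrix(FALSE, n_genes, n_cells, dimnames = dimnames(truth))
  live <- seq_len(n_cyc + n_pl + n_reg)
  for (g in live) {
    mode <- rbinom(n_cells, 1L, pi_gene[g])
    v <- rlnorm(n_cells, meanlog = ifelse(mode == 1L, mu_hi, mu_lo),
                sdlog = sigma)
    drop <- runif(n_cells) < dropout
    v[drop] <- 0
    truth[g, ] <- mode
    vals[g, ] <- v
    dropped[g, ] <- drop
  }
  list(matrix = vals, truth = truth, dropped = dropped,
       flat_genes = if (n_flat > 0L) genes[(n_cyc + n_pl + n_reg + 1L):n_genes]
                    else character(0),
       spec = list(n_genes = n_genes, n_cells = n_cells, mu_lo = mu_lo,
                   mu_hi = mu_hi, sigma = sigma, pi_high = pi_high,
                   dropout = dropout, n_flat = n_flat,
                   cyclin_genes = cyclin_genes, cyclin_pi = cyclin_pi,
                   planted = planted,
                   seed = if (is.null(seed)) NA else seed))
}
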