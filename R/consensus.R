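# Consensus building blocks for R-protein domains. These synthetic consensus
# sequences carry the field-standard sequence landmarks of each domain (P-loop
# GxGGxGKTT, kinase-2 LLVLDDVW and GLPL in the NB-ARC; the TIR fold core; a
# heptad-rich coiled-coil with an EDVID-like patch; the RPW8 helical bundle)
# and anchor both the bundled scoring profiles and the synthetic-data
# generator, so that generated proteins close the loop through the domain
# scanner.

NB_CONSENSUS <- paste0(
  "VGLEGIVKEVLEKLDSPELRVIPIVGMGGIGKTTLAQLVYNDPRVQEHFDLKAWVCVSDD",
  "FDVKRLTKEIIESATGKACELNNLDALQVKLKEILQGKRFLIVLDDVWNEDRDKWEALRT",
  "PLNAGAPGSKIIVTTRNESVALMMGTVPPYHLSGLSEDDCWSLFKQRAFGPNEEEQVELE",
  "EIGKEIVKKCGGLPLAAKTL")  # 200 aa, the average NB domain length

TIR_CONSENSUS <- paste0(
  "YDVFLSFRGEDTRKTFTSHLYEALKDRGIHTFIDDEELRRGDEISPALLKAIEESRIAII",
  "VFSKNYASSTWCLDELVKILECKEKYGQIVIPVFYDVDPSEVRKQTGSFGKAFAKHEERF",
  "KDDVEKMEEVQRWRIALTEAANLSG")  # 145 aa

CC_CONSENSUS <- paste0(
  "MAEALVGGALLSALLQVLFDRLASPEVVDFIRGKKLDEKLLKKLKTTLLSLQAVLNDAEQKQ")  # 62 aa

RPW8_CONSENSUS <- paste0(
  "MGEAIVSEVLGRLGDMLIEEAVFLGGVRDQVEWLKRELRWMQSFLKDAEAKQAGNERVRN",
  "WVSEIRDVAYDAEDVIDTYILKVASRRRGGFLGFLHKLSH")  # 100 aa

# Twelve LxxLxLxx repeat units (96 aa): the degenerate leucine-rich repeat
# consensus used for generation; the scanner requires >= 3 of the 4
# leucine-type positions per 8-residue frame.
LRR_UNITS <- c("LSELDLSG", "LKELNLSR", "LTKLILSN", "LVELDLSE",
               "LGSLNLSH", "LRELILSK", "LSKLDLSN", "LEELNLSG",
               "LTELILSE", "LKGLDLSR", "LSELNLSK", "LRELDLSG")
LRR_CONSENSUS <- paste(LRR_UNITS, collapse = "")

# Short linkers placed between domains in generated proteins.
LINKER_NT_NB <- "SSRETDPRST"
LINKER_NB_LRR <- "GEKSTNDPKG"

consensus_block <- function(kind) {
  switch(kind,
         NB = NB_CONSENSUS, TIR = TIR_CONSENSUS, CC = CC_CONSENSUS,
         RPW8 = RPW8_CONSENSUS, LRR = LRR_CONSENSUS,
         abort(sprintf("unknown consensus block '%s'", kind)))
}
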