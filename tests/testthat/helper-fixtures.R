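# Shared fixtures and independent oracles for the test suite. Oracles here
# are deliberately naive (brute force / closed form) and never call the
# implementation paths they check.

tinyEventMatrix <- function(n = 10, channels = c("FSC-A", "CD3"), seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(abs(rnorm(n * length(channels), 100, 10)), n,
                dimnames = list(NULL, channels))
    EventMatrix(m, sampleId = "tiny")
  })
}

# Minimal hand-built FCS 3.1 writer, independent of writeFCS, with control
# over $PnS; used to test channel-name precedence and reader behaviour.
writeRawFCS <- function(path, mat, pnn, pns = NULL) {
  n <- nrow(mat); p <- ncol(mat)
  kv <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0", "$BEGINSTEXT", "0",
          "$ENDSTEXT", "0", "$BEGINDATA", "0000000000", "$ENDDATA", "0000000000",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", p, "$TOT", n)
  for (i in seq_len(p)) {
    kv <- c(kv, sprintf("$P%dB", i), "32", sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), pnn[i], sprintf("$P%dR", i), "262144")
    if (!is.null(pns)) kv <- c(kv, sprintf("$P%dS", i), pns[i])
  }
  text <- paste0("/", paste(kv, collapse = "/"), "/")
  textStart <- 58
  textEnd <- textStart + nchar(text) - 1
  dataStart <- textEnd + 1
  dataEnd <- dataStart + 4 * n * p - 1
  text <- sub("0000000000", sprintf("%010d", dataStart), text, fixed = TRUE)
  text <- sub("0000000000", sprintf("%010d", dataEnd), text, fixed = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", textStart, textEnd,
                    dataStart, dataEnd, 0L, 0L), con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4, endian = "little")
  path
}

# Brute-force F-measure from an explicitly tabulated confusion matrix.
bruteForceF <- function(a, b) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) tp <- tp + 1
    if (a[i] && !b[i]) fp <- fp + 1
    if (!a[i] && b[i]) fn <- fn + 1
  }
  if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

# Adjusted Rand index between two partitions (closed form on the
# contingency table); independent check for the clustering.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp <- si * sj / n2
  (sij - exp) / ((si + sj) / 2 - exp)
}

# Balanced-design ANOVA (method-of-moments) variance components for the
# technician design: oracle for the REML fit.
anovaVarComponents <- function(design) {
  fit <- stats::aov(value ~ factor(control_id) + factor(technician_id),
                    data = design)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msTech <- ms[2]; msRes <- ms[3]
  nPerTech <- nrow(design) / length(unique(design$technician_id))
  c(var_inter = max((msTech - msRes) / nPerTech, 0), var_intra = msRes)
}

# One-dimensional shoulder-cut oracle: dense scan of the same KDE for the
# first grid point right of the tallest peak where density drops to the
# threshold fraction.
shoulderScanOracle <- function(x, frac = 0.05) {
  d <- stats::density(x, bw = stats::bw.nrd0(x), n = 512,
                      from = min(x), to = max(x))
  pk <- which.max(d$y)
  for (i in seq(pk, length(d$y))) {
    if (d$y[i] <= frac * d$y[pk]) return(d$x[i])
  }
  d$x[length(d$x)]
}

smallPanelSpec <- function(n = 8000) defaultPanelSpec(nEvents = n)

hipTemplate <- function() {
  parseGatingTemplate(system.file("extdata", "hip_template_synthetic.csv",
                                  package = "cytoHybrid"))
}
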