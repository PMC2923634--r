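# Independent brute-force oracles and binary fixtures built at test time.

# Double-loop community similarity: scalar arithmetic only, independent of
# the vectorized/compiled implementation paths.
bruteForceSimilarity <- function(membersA, membersB, data, sigma) {
  total <- 0
  for (i in membersA) {
    for (j in membersB) {
      d2 <- 0
      for (k in seq_len(ncol(data)))
        d2 <- d2 + (data[i, k] - data[j, k])^2
      total <- total + exp(-d2 / (2 * sigma^2))
    }
  }
  total
}

# Full brute-force similarity matrix over a sampling result (diagonal runs
# over all ordered pairs including i = j).
bruteForceSimilarityMatrix <- function(communities, data, sigma) {
  m <- length(communities)
  S <- matrix(0, m, m)
  for (a in seq_len(m))
    for (b in seq_len(m))
      S[a, b] <- bruteForceSimilarity(communities[[a]], communities[[b]],
                                      data, sigma)
  S
}

# Minimal FCS 3.1 writer (list mode, float32, little endian) used to build
# read-back fixtures; binary files live only in tempdir().
writeMiniFCS <- function(path, mat, channelNames = colnames(mat)) {
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(ncol(mat)))
  npar <- ncol(mat)
  ntot <- nrow(mat)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", npar, "$TOT", ntot)
  for (i in seq_len(npar))
    kw <- c(kw, paste0("$P", i, "N"), channelNames[i],
            paste0("$P", i, "B"), 32, paste0("$P", i, "R"), 262144)
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  textBeg <- 58L
  textEnd <- textBeg + nchar(text) - 1L
  dataBeg <- textEnd + 1L
  dataEnd <- dataBeg + 4L * npar * ntot - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    textBeg, textEnd, dataBeg, dataEnd, 0L, 0L)
  stopifnot(nchar(header) == 58L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

# Tiny labelled two-Gaussian dataset for end-to-end checks.
twoGaussians <- function(nPer = 2000, gap = 20, seed = 42) {
  set.seed(seed)
  events <- rbind(
    cbind(stats::rnorm(nPer), stats::rnorm(nPer)),
    cbind(stats::rnorm(nPer, gap), stats::rnorm(nPer)))
  colnames(events) <- c("x", "y")
  list(events = events, truth = rep(1:2, each = nPer))
}
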