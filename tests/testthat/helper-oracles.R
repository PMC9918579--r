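# Independent straightforward reference implementations used as oracles.
# These follow the textbook definitions in plain R on integer code points
# and are deliberately kept separate from the package's C++ routines.

oracle_jaro <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  la <- length(x)
  lb <- length(y)
  if (la == 0 && lb == 0) return(0)
  if (la == 0 || lb == 0) return(1)
  window <- max(floor(max(la, lb) / 2) - 1, 0)
  ymatched <- rep(FALSE, lb)
  xmatch <- integer(0)
  for (i in seq_len(la)) {
    lo <- max(1, i - window)
    hi <- min(lb, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!ymatched[j] && x[i] == y[j]) {
        ymatched[j] <- TRUE
        xmatch <- c(xmatch, i)
        break
      }
    }
  }
  m <- length(xmatch)
  if (m == 0) return(1)
  half_t <- sum(x[xmatch] != y[which(ymatched)])
  sim <- (m / la + m / lb + (m - half_t / 2) / m) / 3
  1 - sim
}

oracle_levenshtein <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  la <- length(x)
  lb <- length(y)
  if (la == 0 && lb == 0) return(0)
  d <- matrix(0L, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[la + 1, lb + 1] / max(la, lb)
}

oracle_osa <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  la <- length(x)
  lb <- length(y)
  if (la == 0 && lb == 0) return(0)
  d <- matrix(0L, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      v <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
               d[i, j] + (x[i] != y[j]))
      if (i > 1 && j > 1 && x[i] == y[j - 1] && x[i - 1] == y[j])
        v <- min(v, d[i - 1, j - 1] + 1L)
      d[i + 1, j + 1] <- v
    }
  }
  d[la + 1, lb + 1] / max(la, lb)
}

# Character-level text-editor replay: the oracle for backspace correction.
oracle_editor <- function(keys) {
  s <- ""
  for (k in keys) {
    if (k == "BACKSPACE") {
      if (nchar(s) > 0) s <- substr(s, 1, nchar(s) - 1)
    } else if (!(k %in% c("BACKSPACE", "SPACE", "ENTER", "SHIFT",
                          "CAPSLOCK", "OTHER"))) {
      s <- paste0(s, k)
    }
  }
  s
}

random_string_pair <- function(max_len = 12,
                               alphabet = c(LETTERS, "Ä", "Ö", "Ü", "ß")) {
  lens <- sample(0:max_len, 2, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(alphabet, l, replace = TRUE), collapse = ""), character(1))
}
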