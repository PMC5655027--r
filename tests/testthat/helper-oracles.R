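# Independent brute-force oracles and small fixture builders. These share
# no code with the package implementations they check.

# --- CIGAR: character-by-character expansion ------------------------------
brute_reference_span <- function(cigar) {
  lens <- as.integer(strsplit(gsub("[MIDNSHP=X]", " ", cigar), " ")[[1]])
  ops <- strsplit(gsub("[0-9]", "", cigar), "")[[1]]
  total <- 0L
  for (i in seq_along(ops)) {
    total <- total + sum(rep(ops[i] %in% c("M", "=", "X", "D", "N"), lens[i]))
  }
  total
}

random_cigar <- function() {
  n_ops <- sample(1:5, 1)
  ops <- sample(c("M", "I", "D", "S", "=", "X"), n_ops, replace = TRUE)
  # keep it structurally valid: start/end clips only, at least one M
  ops <- c(ops[ops != "S"], "M")
  lens <- sample(1:9, length(ops), replace = TRUE)
  paste0(paste0(lens, ops, collapse = ""), "")
}

# --- SAM fixture builder --------------------------------------------------
write_sam_fixture <- function(records, contigs, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)))
  writeLines(c(hdr, records), path)
  path
}

sam_record <- function(qname, flag, rname, pos, cigar, seq, mapq = 60) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
          qname, flag, rname, pos, mapq, cigar, seq)
}

# --- naive MCL (explicit loops; same parameters, independent code) --------
naive_mcl <- function(adj, inflation = 2, max_iter = 200, prune = 1e-6,
                      tol = 1e-8) {
  n <- nrow(adj)
  M <- adj
  for (j in 1:n) {
    mx <- 0
    for (i in 1:n) if (i != j && M[i, j] > mx) mx <- M[i, j]
    M[j, j] <- if (mx == 0) 1 else mx
  }
  for (j in 1:n) M[, j] <- M[, j] / sum(M[, j])
  for (it in 1:max_iter) {
    prev <- M
    nxt <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      s <- 0
      for (k in 1:n) s <- s + M[i, k] * M[k, j]
      nxt[i, j] <- s
    }
    for (i in 1:n) for (j in 1:n) nxt[i, j] <- nxt[i, j]^inflation
    for (i in 1:n) for (j in 1:n) if (nxt[i, j] < prune) nxt[i, j] <- 0
    for (j in 1:n) nxt[, j] <- nxt[, j] / sum(nxt[, j])
    M <- nxt
    if (max(abs(M - prev)) < tol) break
  }
  assign_to <- integer(n)
  attractors <- which(diag(M) > prune)
  for (j in 1:n) {
    sup <- attractors[M[attractors, j] > 0]
    assign_to[j] <- if (length(sup) == 0) j else sup[which.max(M[sup, j])]
  }
  # return the partition as a canonical list of sorted member index vectors
  unname(lapply(split(seq_len(n), assign_to), sort))
}

# canonicalize a partition given as list of name vectors
canon_partition <- function(groups, nodes) {
  parts <- unname(lapply(groups, function(g) sort(match(g, nodes))))
  parts[order(vapply(parts, `[`, integer(1), 1))]
}

# --- naive complete-linkage agglomeration: merge heights ------------------
naive_complete_heights <- function(dmat) {
  n <- nrow(dmat)
  active <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    bestd <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        d <- max(dmat[active[[i]], active[[j]]])
        if (d < bestd) {
          bestd <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}

# --- misc -----------------------------------------------------------------
table2_path <- function() system.file("extdata", "table2_sulfurovum.tsv",
                                      package = "magvar")
table1_path <- function() system.file("extdata", "table1_samples.tsv",
                                      package = "magvar")

# pileup from hand-built alignment rows
make_alignments <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(read_id = r[[1]], contig_id = r[[2]], pos = as.integer(r[[3]]),
               flag = 0L, mapq = 60L, cigar = r[[4]], seq = r[[5]],
               stringsAsFactors = FALSE)
  }))
}
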