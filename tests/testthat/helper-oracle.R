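## Independent brute-force oracles. These deliberately share no code with the
## package: the repeat scanner walks every (start, unit-length) pair and
## extends character by character; the class counter is a union-find over all
## 4^k strings.

## exhaustive perfect-repeat scanner; returns the same record shape as
## findPerfectSSRs so results can be compared exactly
oracleMine <- function(s, minRep = c(12L, 6L, 5L, 5L, 4L, 4L)) {
    s <- toupper(s)
    x <- strsplit(s, "", fixed = TRUE)[[1L]]
    ok <- x %in% c("A", "C", "G", "T")
    n <- length(x)
    starts <- integer(); ks <- integer(); counts <- integer()
    for (st in seq_len(n)) {
        for (k in 1:6) {
            if (st + k * minRep[k] - 1L > n) break
            if (any(!ok[st:(st + k - 1L)])) next
            ## left-anchored: cannot slide the window one base left
            if (st > 1L && ok[st - 1L] && x[st - 1L] == x[st + k - 1L]) next
            j <- st + k
            while (j <= n && ok[j] && x[j] == x[j - k]) j <- j + 1L
            cnt <- (j - st) %/% k
            if (cnt < minRep[k]) next
            ## primitive: no shorter period d dividing k
            prim <- TRUE
            for (d in seq_len(k - 1L)) {
                if (k %% d != 0L) next
                if (all(x[st:(st + k - 1L)] ==
                        x[st + (seq_len(k) - 1L) %% d])) { prim <- FALSE; break }
            }
            if (!prim) next
            starts <- c(starts, st); ks <- c(ks, k); counts <- c(counts, cnt)
        }
    }
    if (!length(starts))
        return(data.frame(start = integer(), end = integer(),
                          observed_unit = character(),
                          unit_length = integer(), repeat_count = integer(),
                          stringsAsFactors = FALSE))
    spans <- ks * counts
    o <- order(starts, -spans)
    starts <- starts[o]; ks <- ks[o]; counts <- counts[o]; spans <- spans[o]
    keep <- logical(length(starts)); lastEnd <- 0L
    for (i in seq_along(starts)) {
        if (starts[i] > lastEnd) {
            keep[i] <- TRUE
            lastEnd <- starts[i] + spans[i] - 1L
        }
    }
    data.frame(start = starts[keep], end = starts[keep] + spans[keep] - 1L,
               observed_unit = substring(s, starts[keep],
                                         starts[keep] + ks[keep] - 1L),
               unit_length = ks[keep], repeat_count = counts[keep],
               stringsAsFactors = FALSE)
}

## union-find partition of all primitive length-k units under one-step
## rotation + reverse complement; returns the number of classes
oracleClassCount <- function(k) {
    units <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                         stringsAsFactors = FALSE))
    prim <- vapply(units, function(u) {
        for (d in seq_len(k - 1L))
            if (k %% d == 0L && strrep(substr(u, 1L, d), k %/% d) == u)
                return(FALSE)
        TRUE
    }, logical(1))
    units <- units[prim]
    idx <- seq_along(units); names(idx) <- units
    parent <- idx
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    link <- function(a, b) {
        ra <- findRoot(a); rb <- findRoot(b)
        if (ra != rb) parent[ra] <<- rb
    }
    for (u in units) {
        rot <- paste0(substr(u, 2L, k), substr(u, 1L, 1L))
        rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", u), "")[[1L]]),
                    collapse = "")
        link(idx[[u]], idx[[rot]])
        link(idx[[u]], idx[[rc]])
    }
    length(unique(vapply(idx, findRoot, integer(1))))
}

## random test sequences: a mix of uniform ACGT, repeat-prone two-letter
## stretches, Ns and lowercase, to stress run boundaries
randomTestSequence <- function(maxLen = 300L) {
    n <- sample(20:maxLen, 1L)
    mode <- sample(1:4, 1L)
    chars <- switch(mode,
        sample(c("A", "C", "G", "T"), n, replace = TRUE),
        sample(c("A", "C"), n, replace = TRUE),
        sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
        sample(c("a", "t", "G", "C"), n, replace = TRUE,
               prob = c(0.4, 0.4, 0.1, 0.1)))
    paste(chars, collapse = "")
}

ssrKey <- function(df) {
    sprintf("%d:%d:%s:%d", df$start, df$end, toupper(df$observed_unit),
            df$repeat_count)
}
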