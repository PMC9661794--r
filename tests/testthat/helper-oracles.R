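# Independent oracles and small fixture writers used across the suite.

# brute-force interval merge: repeatedly collapse ANY same-class pair that
# overlaps or is within gap_max, until a fixed point; order by midpoint
bruteMerge <- function(hits, gap_max) {
  units <- lapply(seq_len(nrow(hits)), function(i)
    list(cls = hits$domain_class[i], s = hits$start[i], e = hits$end[i]))
  repeat {
    merged <- FALSE
    for (i in seq_along(units)) {
      for (j in seq_along(units)) {
        if (j <= i) next
        a <- units[[i]]; b <- units[[j]]
        if (a$cls != b$cls) next
        gap <- max(a$s, b$s) - min(a$e, b$e) - 1
        if (gap <= gap_max) {
          units[[i]] <- list(cls = a$cls, s = min(a$s, b$s),
                             e = max(a$e, b$e))
          units[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  df <- data.frame(letter = vapply(units, `[[`, "", "cls"),
                   start = vapply(units, `[[`, 0, "s"),
                   end = vapply(units, `[[`, 0, "e"))
  mid <- (df$start + df$end) / 2
  df <- df[order(mid, df$start, df$letter), ]
  rownames(df) <- NULL
  df
}

# brute-force Pearson correlation from centered sums
brutePearson <- function(x, y) {
  xc <- x - sum(x) / length(x)
  yc <- y - sum(y) / length(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# write a domain-hit table file from rows of (protein, domain, start, end,
# evalue)
writeHitFile <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, function(r)
    paste(r, collapse = "\t"), character(1)), path)
  path
}

randomHitSet <- function(n_hits) {
  starts <- sample.int(1500, n_hits, replace = TRUE)
  data.frame(protein_id = "p",
             domain_class = sample(c("N", "T", "C", "L", "R"), n_hits,
                                   replace = TRUE),
             start = starts,
             end = starts + sample.int(300, n_hits, replace = TRUE) - 1L,
             evalue = 0, source = "x", stringsAsFactors = FALSE)
}
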