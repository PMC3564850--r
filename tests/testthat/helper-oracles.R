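# Random generators and independent brute-force oracles used across the suite.

random_list_table <- function(name, n_rows = 20, n_value = 1, n_label = 1,
                              blank_prob = 0.15) {
  ids <- sprintf("e%02d", sample.int(n_rows + 5, n_rows, replace = TRUE))
  rec <- data.frame(element = ids, stringsAsFactors = FALSE)
  schema <- data.frame(name = character(), kind = character(), stringsAsFactors = FALSE)
  for (j in seq_len(n_value)) {
    a <- paste0("v", j)
    col <- round(runif(n_rows, -1, 1), 3)
    col[runif(n_rows) < blank_prob] <- NA_real_
    rec[[a]] <- col
    schema <- rbind(schema, data.frame(name = a, kind = "value"))
  }
  for (j in seq_len(n_label)) {
    a <- paste0("t", j)
    col <- sample(c("P6", "P10", "E16", "P2", "4wk"), n_rows, replace = TRUE)
    col[runif(n_rows) < blank_prob] <- ""
    rec[[a]] <- col
    schema <- rbind(schema, data.frame(name = a, kind = "label"))
  }
  source_table(name, "list", "element", schema, rec)
}

random_filter_set <- function(table, max_groups = 2) {
  schema <- table$schema
  n_g <- sample.int(max_groups + 1, 1) - 1L   # 0..max_groups groups
  attrs <- sample(schema$name, min(n_g, nrow(schema)))
  groups <- lapply(attrs, function(a) {
    kind <- schema$kind[schema$name == a]
    if (kind == "value") {
      n_c <- sample(1:2, 1)
      crits <- lapply(seq_len(n_c), function(i) {
        criterion(a, operator = sample(c("<", "<=", ">", ">=", "=="), 1),
                  value = round(runif(1, -1, 1), 2))
      })
    } else {
      crits <- list(criterion(a, tags = sample(c("P6", "P10", "E16", "P2", "4wk"),
                                               sample(1:3, 1))))
    }
    list(criteria = crits, logic = sample(c("all", "any"), 1))
  })
  filter_set(table$name, stats::setNames(groups, attrs))
}

# Row-by-row predicate oracle, written independently of criterion_mask:
# scalar evaluation with explicit blank handling.
oracle_row_passes <- function(row, fs) {
  for (a in names(fs$groups)) {
    g <- fs$groups[[a]]
    hits <- vapply(g$criteria, function(cr) {
      cell <- row[[cr$attribute]]
      if (cr$form == "comparison") {
        if (is.na(cell)) return(FALSE)
        switch(cr$operator,
               "<"  = cell < cr$value,
               "<=" = cell <= cr$value,
               ">"  = cell > cr$value,
               ">=" = cell >= cr$value,
               "==" = isTRUE(abs(cell - cr$value) <= 1e-9))
      } else {
        !is.na(cell) && nzchar(cell) && cell %in% cr$tags
      }
    }, logical(1))
    ok <- if (g$logic == "any") any(hits) else all(hits)
    if (!ok) return(FALSE)
  }
  TRUE
}

oracle_filter_rows <- function(table, fs) {
  vapply(seq_len(nrow(table$records)),
         function(i) oracle_row_passes(as.list(table$records[i, , drop = FALSE]), fs),
         logical(1))
}

# Set-membership integration oracle: count sources containing each element.
oracle_integrate_lists <- function(element_sets) {
  all_el <- sort(unique(unlist(element_sets)))
  do.call(rbind, lapply(all_el, function(e) {
    src <- sort(names(element_sets)[vapply(element_sets, function(s) e %in% s, logical(1))])
    data.frame(element = e, reoccurrence = length(src),
               sources = paste(src, collapse = ";"), stringsAsFactors = FALSE)
  }))
}

# Hypergeometric upper-tail by direct enumeration with choose().
oracle_hyper_tail <- function(q, hits_total, universe, selected) {
  ks <- max(q, 0):min(selected, hits_total)
  ks <- ks[selected - ks <= universe - hits_total]
  sum(choose(hits_total, ks) * choose(universe - hits_total, selected - ks)) /
    choose(universe, selected)
}

make_network_tables <- function(edge_lists) {
  # edge_lists: named list of 2-column matrices/data.frames
  lapply(names(edge_lists), function(nm) {
    e <- as.data.frame(edge_lists[[nm]], stringsAsFactors = FALSE)
    names(e) <- c("node_a", "node_b")
    source_table(nm, "network", c("node_a", "node_b"), records = e)
  })
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
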