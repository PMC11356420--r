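# Optimal rectangular assignment (Jonker-Volgenant shortest augmenting path).
#
# Minimises total cost of a 1:1 assignment of rows to columns, nrow <= ncol.
# Infeasible pairs are encoded as Inf; if no finite-cost assignment exists the
# function reports the row at which augmentation failed. This is the engine
# behind matched-control selection, where the paper-style matching criteria
# (age and enrollment tolerances, exact race/ethnicity) define the finite
# entries and the tolerance-scaled gap sum defines the cost.

solve_assignment <- function(cost) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  if (nr > nc) abort("assignment requires nrow(cost) <= ncol(cost)")
  u <- numeric(nr)
  v <- numeric(nc)
  col4row <- rep(NA_integer_, nr)
  row4col <- rep(NA_integer_, nc)

  for (cur_row in seq_len(nr)) {
    min_dist <- rep(Inf, nc)
    path <- rep(NA_integer_, nc)
    remaining <- rep(TRUE, nc)
    visited_rows <- cur_row
    min_val <- 0
    i <- cur_row
    sink <- NA_integer_
    while (is.na(sink)) {
      idx <- which(remaining)
      red <- min_val + cost[i, idx] - u[i] - v[idx]
      upd <- red < min_dist[idx]
      if (any(upd)) {
        min_dist[idx[upd]] <- red[upd]
        path[idx[upd]] <- i
      }
      j <- idx[which.min(min_dist[idx])]
      min_val <- min_dist[j]
      if (!is.finite(min_val)) {
        return(list(feasible = FALSE, failed_row = cur_row))
      }
      remaining[j] <- FALSE
      if (is.na(row4col[j])) {
        sink <- j
      } else {
        i <- row4col[j]
        visited_rows <- c(visited_rows, i)
      }
    }
    # dual updates (scanned rows/columns only)
    u[cur_row] <- u[cur_row] + min_val
    for (r in setdiff(visited_rows, cur_row)) {
      u[r] <- u[r] + min_val - min_dist[col4row[r]]
    }
    scanned <- which(!remaining)
    v[scanned] <- v[scanned] - (min_val - min_dist[scanned])
    # augment along the alternating path back to cur_row
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      tmp <- col4row[i]
      col4row[i] <- j
      if (i == cur_row) break
      j <- tmp
    }
  }

  total <- sum(cost[cbind(seq_len(nr), col4row)])
  list(feasible = TRUE, col4row = col4row, total_cost = total)
}
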