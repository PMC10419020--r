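# Independent brute-force hydrogen-bond scan.
#
# Works directly off the raw atom table and sidecar annotation with plain
# double loops, re-deriving donors, acceptors, classes and molecule labels
# without touching the package's detection code paths.
brute_force_hbonds <- function(gen, cutoff = 2.0) {
  at <- gen$atoms
  sc <- gen$sidecar
  pos <- function(i) c(at$x[i], at$y[i], at$z[i])
  mol <- character(nrow(at))
  mol[sc$membership$guest] <- "guest"
  mol[sc$membership$cd1] <- "cd1"
  if (length(sc$membership$cd2)) mol[sc$membership$cd2] <- "cd2"

  donors <- list()
  for (s in sc$sites) {
    if (at$element[s$substituent] == "H") {
      donors[[length(donors) + 1]] <- list(o = s$oxygen, h = s$substituent,
                                           class = "cd_hydroxyl_OH")
    }
  }
  donors[[length(donors) + 1]] <- list(o = sc$guest$ph1$o, h = sc$guest$ph1$h,
                                       class = "phenol_OH")
  donors[[length(donors) + 1]] <- list(o = sc$guest$ph2$o, h = sc$guest$ph2$h,
                                       class = "phenol_OH")

  acceptors <- list(list(i = sc$guest$fe, class = "fe"))
  acceptors[[2]] <- list(i = sc$guest$ph1$o, class = "phenol_O")
  acceptors[[3]] <- list(i = sc$guest$ph2$o, class = "phenol_O")
  acceptors[[4]] <- list(i = sc$guest$imide_o[1], class = "imide_O1")
  acceptors[[5]] <- list(i = sc$guest$imide_o[2], class = "imide_O2")
  for (s in sc$sites) {
    if (at$element[s$substituent] == "H") {
      acceptors[[length(acceptors) + 1]] <- list(i = s$oxygen,
                                                 class = "cd_hydroxyl_O")
    }
  }
  for (i in sc$cd_acceptors$ether) {
    acceptors[[length(acceptors) + 1]] <- list(i = i, class = "cd_ether_O")
  }
  for (i in sc$cd_acceptors$anomeric) {
    acceptors[[length(acceptors) + 1]] <- list(i = i, class = "cd_anomeric_O")
  }

  allowed <- list(
    cd_hydroxyl_OH = c("fe", "imide_O1", "imide_O2", "phenol_O"),
    phenol_OH = c("cd_hydroxyl_O", "cd_ether_O", "cd_anomeric_O")
  )
  rows <- list()
  for (d in donors) {
    for (a in acceptors) {
      if (!a$class %in% allowed[[d$class]]) next
      if (mol[d$h] == mol[a$i]) next
      if (a$i == d$o || a$i == d$h) next
      len <- sqrt(sum((pos(a$i) - pos(d$h))^2))
      if (len <= cutoff) {
        rows[[length(rows) + 1]] <- data.frame(
          donor_heavy = d$o, hydrogen = d$h, acceptor = a$i, length = len
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(donor_heavy = integer(), hydrogen = integer(),
                      acceptor = integer(), length = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$donor_heavy, out$hydrogen, out$acceptor), , drop = FALSE]
}

# Random geometry fixture: random methylation state plus 0-4 planted
# contacts at distances straddling the 2 A cutoff.
random_fixture <- function(seed) {
  set.seed(seed)
  n_cd <- sample(1:2, 1)
  state <- runif(21 * n_cd) < 0.4
  n_contact <- sample(0:4, 1)
  contacts <- list()
  free_sites <- which(!state)
  free_phenols <- c("ph1", "ph2")
  guest_acc <- c("fe", "imide_o:1", "imide_o:2")
  # each phenol serves as either a donor or an acceptor, never both
  for (p in 1:2) {
    if (runif(1) < 0.5) {
      guest_acc <- c(guest_acc, sprintf("phenol_o:%d", p))
      free_phenols <- setdiff(free_phenols, sprintf("ph%d", p))
    }
  }
  for (k in seq_len(n_contact)) {
    d <- runif(1, 1.5, 2.5)
    if ((runif(1) < 0.7 || !length(free_phenols)) && length(free_sites)) {
      donor <- sample(free_sites, 1)
      free_sites <- setdiff(free_sites, donor)
      contacts[[length(contacts) + 1]] <-
        list(donor = donor, acceptor = sample(guest_acc, 1), distance = d)
    } else if (length(free_phenols)) {
      donor <- free_phenols[1]
      free_phenols <- free_phenols[-1]
      cd <- sample(seq_len(n_cd), 1)
      acc <- sprintf("cd_%s:%d:%d", sample(c("ether", "anomeric"), 1), cd,
                     sample(1:7, 1))
      contacts[[length(contacts) + 1]] <-
        list(donor = donor, acceptor = acc, distance = d)
    }
  }
  make_geometry(geometry_spec(n_cd = n_cd, state = state, contacts = contacts,
                              seed = seed))
}

# Apply a rigid rotation + translation to a generated fixture and re-annotate.
rigid_transform <- function(gen, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  Q <- Rx %*% Ry %*% Rz
  shift <- runif(3, -20, 20)
  xyz <- as.matrix(gen$atoms[, c("x", "y", "z")]) %*% t(Q)
  atoms <- gen$atoms
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  annotate(atoms, gen$sidecar)
}

bond_key <- function(b) {
  b <- b[order(b$donor_heavy, b$hydrogen, b$acceptor), , drop = FALSE]
  sprintf("%d-%d-%d", b$donor_heavy, b$hydrogen, b$acceptor)
}
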