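# Minimal hand-built realizations for exercising the Markov engine directly.

zero_shared <- function(recurrence_mortality_rr = 1) {
  list(state_costs = c(healthy = 0, acute_gu = 0, acute_gi = 0, late_gu = 0,
                       late_gi = 0, recurrence = 0, dead = 0),
       salvage_cost = 0,
       disutilities = c(acute_gu = 0, acute_gi = 0, late_gu = 0,
                        late_gi = 0, recurrence = 0),
       recurrence_mortality_rr = recurrence_mortality_rr)
}

make_arm <- function(name = "SBRT", acute_gu = 0, acute_gi = 0, late_gu = 0,
                     late_gi = 0, recurrence = 0, mortality_rr = 1,
                     index_cost = 0) {
  list(name = name,
       p = c(acute_gu = acute_gu, acute_gi = acute_gi, late_gu = late_gu,
             late_gi = late_gi, recurrence = recurrence),
       mortality_rr = mortality_rr, index_cost = index_cost)
}

# constant annual death probability q at every age
const_life_table <- function(q) {
  life_table(data.frame(age = 40:100, q_annual = q))
}

# a random but feasible arm realization, for property-style loops
random_arm <- function() {
  make_arm(acute_gu = runif(1, 0, 0.5), acute_gi = runif(1, 0, 0.4),
           late_gu = runif(1, 0, 0.02), late_gi = runif(1, 0, 0.02),
           recurrence = runif(1, 0, 0.05),
           mortality_rr = runif(1, 0.5, 4),
           index_cost = runif(1, 1000, 20000))
}

random_shared <- function() {
  list(state_costs = c(healthy = runif(1, 0, 300),
                       acute_gu = runif(1, 0, 3000),
                       acute_gi = runif(1, 0, 3000),
                       late_gu = runif(1, 0, 1000),
                       late_gi = runif(1, 0, 1000),
                       recurrence = runif(1, 0, 2000), dead = 0),
       salvage_cost = runif(1, 0, 10000),
       disutilities = c(acute_gu = runif(1, 0, 0.2),
                        acute_gi = runif(1, 0, 0.2),
                        late_gu = runif(1, 0, 0.3),
                        late_gi = runif(1, 0, 0.3),
                        recurrence = runif(1, 0, 0.5)),
       recurrence_mortality_rr = runif(1, 1, 3))
}

gompertz_lt <- function() make_life_table(3e-5, 0.085, 40, 100)
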