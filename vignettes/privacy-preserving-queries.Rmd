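---
title: "Privacy-preserving similar-patient queries: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving similar-patient queries: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppcdss)
```

## The clinical question and its estimand

Choosing a therapy for an HIV-1 patient benefits from knowing how the same
therapy fared in patients carrying a similar virus. The relevant genetic
signal is the presence or absence of resistance-associated mutations, so a
viral genotype is modelled as a bit string $v \in \{0,1\}^N$ — one
indicator per relevant mutation position, with $N$ in the low hundreds.
Two genotypes are *similar* when their Hamming distance
$H(v_1, v_2) = |\{i : v_1(i) \neq v_2(i)\}|$ is strictly below a public
threshold $B$.

Treatment effectiveness is summarized by the time-to-treatment-failure
(TTF): the number of days from the start of a therapy to its switch,
discontinuation, or death. For a query genotype $v$ and each treatment
$tr$, the quantity of interest is the mean TTF over similar patients,

$$\overline{TTF}_{tr}(v) \;=\;
  \frac{1}{|\{i : H(v, v_i) < B\}|} \sum_{i\,:\,H(v, v_i) < B} TTF_{tr}(v_i).$$

Patient records are sensitive and held by many clinics; pooling them in
the clear is usually impossible. The package therefore computes this
estimand under secure multiparty computation (MPC): records are
additively secret-shared among $n \geq 2$ non-colluding computing
parties, the query genotype is shared the same way, and only the querying
clinician learns the per-treatment result.

## Protocol stack

**Field and sharing.** All values are embedded in a prime field $F_p$
(default: the 128-bit pseudo-Mersenne prime $p = 2^{128} - 159$; any odd
prime up to 128 bits with $p > 2^{l+\kappa+1}$ works). A secret $x$ is
split into $n$ shares summing to $x \bmod p$, the first $n-1$ uniform, so
any strict subset of shares is exactly uniform — a single party's view
carries no information. Addition, subtraction and multiplication by
public constants are local; a public additive constant is absorbed by
party 1 by convention.

**Multiplication.** Products use Beaver triples $(a, b, c = ab)$ dealt in
an input-independent offline phase by a trusted dealer. One secure
multiplication consumes one triple, opens the two masked differences
$d = x - a$ and $e = y - b$ (uniform, so they leak nothing) and outputs
the local combination $c + d\,b + e\,a + d e$. XOR of shared bits is the
arithmetization $x + y - 2xy$ (one triple), and the Hamming distance of
two shared $N$-bit vectors is the local sum of $N$ XORs — exactly $N$
triples per record, computed once and reused for all treatments.

**Comparison.** The similarity test $d_i < B$ uses statistically masked
bit extraction in the style of Catrina and de Hoogh. With
$x \in [0, 2^l)$ and $0 \le B \le 2^l$, let $y = 2^l + x - B$; then
$x < B$ exactly when bit $l$ of $y$ is 0. The dealer supplies $l$
bitwise-shared low mask bits and $\kappa$ bitwise-shared high bits; the
parties open $y + r_{\text{low}} + 2^l r_{\text{high}}$, recover
$[y \bmod 2^l]$ with a public-versus-shared borrow chain ($l-1$ triples,
one triple per chain step), and take bit $l$ by a local scaled
difference. The masked opening is the only disclosure; because the mask
carries $\kappa$ uniform bits above the data, the statistical leakage is
about $2^{-\kappa}$ (default $\kappa = 40$). Correctness is exact — the
unit tests check the predicate exhaustively.

**The query circuit.** Per record $i$: distance $d_i$ ($N$ triples),
indicator $s_i = [d_i < B]$ ($l - 1$ triples, $l + \kappa$ random bits),
masked TTF $u_i = s_i \cdot ttf_i$ (1 triple), and per treatment $t$ the
accumulations $S_t \mathrel{+}= u_i \cdot \text{onehot}_{i,t}$ and
$C_t \mathrel{+}= s_i \cdot \text{onehot}_{i,t}$ ($2T$ triples). The
parties end holding shares of $(S_t, C_t)$ for all $t$ and open nothing;
the client reconstructs and divides locally.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $p$ | prime modulus | $2^{128}-159$ | must satisfy $p > 2^{l+\kappa+1}$ |
| $n$ | computing parties | 2 | the deployment topology; any $n \ge 2$ |
| $\kappa$ | statistical security (bits) | 40 | leakage of a masked opening $\approx 2^{-\kappa}$ |
| $l$ | comparison bit width | 8 | needs $N < 2^l$; `NA` disables comparisons |
| $B$ | similarity threshold | query input | public, $0 \le B \le N$; strict $d < B$ |
| $N$ | genotype length | 150 (generator) | benchmark range 100–200 |
| $T$ | treatments | 100 (generator) | one-hot encoded |

## Cost model and obliviousness

Every resource count is a function of the circuit shape $(m, N, T)$ and
$(l, \kappa)$ only. Per record the circuit consumes $N + l - 1 + 1 + 2T$
triples and $l + \kappa$ dealer random bits; rounds are $l + 3$
regardless of $m$ because all per-record operations in one layer are
batched into a single message per ordered party pair. `estimate_query_cost()`
is the closed form; a property test pins it to the ledger of a real
execution, so the estimator and the engine cannot drift apart. Counting
each random bit as one triple-equivalent (the standard square-and-open
generation cost), a full-scale query over $m = 20{,}000$ records with
$N = 200$ and $T = 100$ needs
$20{,}000 \times (200 + 7 + 1 + 200 + 48) = 9.12$ million
triple-equivalents — comfortably below the forty-million budget that the
offline phase of the reference deployment was provisioned for.

Obliviousness is tested, not assumed: two runs of identical shape but
different record contents, query genotypes and thresholds must produce
identical ledgers *and* identical per-frame transcript byte counts. The
in-process transport builds the real wire frames (magic, session id,
sequence number, opcode, element count, packed big-endian elements), so
the byte totals are measured on actual message bytes; the socket
transport pushes the same frames through a loopback TCP connection and
must deliver them byte-identically.

## Synthetic cohorts

No real data is used anywhere. The generator draws genotype bit $j$ as an
independent Bernoulli($\pi_j$) (default $\pi_j = 0.05$ everywhere,
reflecting individually uncommon resistance mutations; a per-position
profile can be supplied), treatments uniformly over the manifest, and TTF
from an exponential with mean 365 days rounded to whole days and
truncated at 3650. These choices exercise the pipeline at the benchmark's
scales; they deliberately do *not* model mutation linkage, resistance
rule systems, survival censoring or realistic treatment-assignment
policy. Passing tests therefore certify the cryptographic pipeline — that
the secure computation equals the plaintext estimand on any cohort of
this shape — not the clinical quality of the estimand itself on real
data. An optional planted-effect mode ties expected TTF to the distance
from a hidden per-treatment archetype (halving per $N/4$ mismatches) so
demonstration output is interpretable rather than pure noise.

Cohorts are pure functions of their specification: every actor (cohort
generator, dealer, each party, client) owns a deterministic
xoshiro256** stream derived from an explicit seed and an actor tag. That
generator is a reproducibility device for experiments and tests; a
production deployment would substitute a cryptographically secure
generator behind the same interface.

## Design choices where the design was open

- **Strict `<` versus `at most`.** The estimand's defining formula uses
  strict $H < B$, and that is what both the oracle and the engine
  implement; an inclusive threshold is available by querying $B + 1$.
- **One-hot treatments.** Storing the treatment as a secret-shared
  one-hot vector makes per-treatment matching a single multiplication
  and keeps treatment identity private, at cost linear in $T$; the
  alternative (a shared categorical plus an equality sub-protocol) costs
  more rounds for no privacy gain here.
- **The client learns counts.** The client receives $(S_t, C_t)$ and
  divides locally. Revealing $C_t$ alongside the average is a deliberate,
  explicit disclosure — it avoids MPC division entirely, and the cohort
  size per treatment is itself clinically relevant.
- **Trusted dealer.** The offline phase is a dealer rather than a
  cryptographic triple-generation protocol; this preserves the online
  semantics exactly while keeping the artifact auditable. Accordingly the
  threat model is semi-honest, non-colluding parties; malicious security
  (MAC-authenticated shares, sacrifice checks) is out of scope.
- **Comparison protocol.** Statistical masking was chosen over
  bit-decomposition or garbled-circuit comparison because it is the
  natural home of a dedicated statistical-security parameter and costs
  $O(l)$ triples. Protocol-level costs are implementation-defined and
  bounded by the budget above rather than matched to any particular
  deployment.
- **Absorption conventions.** Public additive constants go to party 1;
  ties in no other place need breaking. Degenerate inputs are defined,
  not crashed: an empty database yields zero-cost, all-zero results;
  $B = 0$ matches nobody; a treatment with no similar patients reports
  "no similar patients" and no division is attempted.
- **Session without comparisons.** Exhaustive small-field protocol tests
  (e.g. all 121 products in $F_{11}$) need fields far below
  $2^{l+\kappa+1}$; a session configured with `l = NA` performs no
  comparisons and hence carries no field-size constraint, keeping the
  invariant "$p > 2^{l+\kappa+1}$ for the comparison parameters in use"
  honest in both directions.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run, among smaller cases: the
end-to-end oracle-equivalence run at $m = 500$, $N = 150$, $T = 10$,
$B = 20$ on the 128-bit field with $\kappa = 40$; the exhaustive
comparison grid $x \in [0, 256) \times B \in [0, 256]$ at $l = 8$,
reduced $\kappa = 8$, $p = 131101$; Beaver multiplication exhaustively
over $F_{11}$ plus 100 random 128-bit cases; obliviousness at $m = 100$
full shape ($N = 150$, $T = 100$); and the dry-run budget at
$m = 20{,}000$. These sizes make each property's evidence exhaustive or
statistically meaningful while a complete run stays in the tens of
seconds on one core.

## Worked example

```{r worked}
records <- data.frame(
  patient_id = c("p1", "p2", "p3", "p4"),
  genotype = c("1010", "1110", "0101", "1010"),
  treatment = c("A", "A", "A", "B"),
  ttf_days = c(100, 200, 50, 300)
)
cfg <- protocol_config(field = prime_field("1fffffffffffffff"),
                       kappa = 10, l = 3, seed = 1)
run_demo(records, B = 2, query_genotype = "1010",
         config = cfg, manifest = c("A", "B"))
```

Hand enumeration confirms it: distances to `1010` are 0, 1, 4, 0; with
$B = 2$ records 1, 2 and 4 are similar; treatment A averages
$(100 + 200)/2 = 150$ days over 2 patients and treatment B averages 300
days over 1.

## Known limitations

Semi-honest security only; no dropout tolerance or recovery; the number
of records, the genotype length, the treatment count and the number of
queries are public by design; repeated queries with varied $B$ or
genotype are not rate-limited or audited, so a malicious *client*
could in principle triangulate — mitigations (query budgets, noise) are
deployment policy, outside this package; and the Hamming metric on
indicator bits is a proof-of-concept similarity, standing in for
clinically calibrated rule-based metrics.
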