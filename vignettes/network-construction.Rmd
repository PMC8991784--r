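---
title: "Constructing patient-sharing physician networks from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing patient-sharing physician networks from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimsnet)
library(data.table)
```

## The problem

In health systems without gatekeeping — Germany's ambulatory sector being
the motivating case — patients choose their office-based physicians freely,
and no formal structure records which physicians actually co-manage the same
people. Yet interventions that aim to improve care coordination (facilitated
peer-review meetings, quality circles, accountable-care pilots) need exactly
that: groups of physicians who genuinely share a patient population.
`claimsnet` implements a five-step social-network-analysis pipeline that
derives such informal networks from routine billing data:

1. **Units**: vertices are individual physicians; an edge connects two
   physicians through the patients they have in common.
2. **Provider population**: physicians of specialties with little direct
   patient contact (laboratory medicine, pathology, radiology, ...) or
   caring for out-of-scope populations (pediatrics) are excluded, because
   their high patient volumes would create edges that do not reflect
   joint care.
3. **Patient population**: the cohort is restricted to adults carrying at
   least one of 14 ambulatory-care-sensitive diagnosis groups, validated by
   claims coding rules (below); dialysis patients are excluded, and only
   billing codes approximating face-to-face contact count.
4. **Network identification**: the weighted patient-sharing graph is
   thresholded and decomposed into communities of bounded size by iterated
   modularity maximisation.
5. **Patient allocation**: each cohort patient is attributed to the single
   network holding a strict majority of their treatment days — their
   *usual provider network* — or left unallocated.

The package implements every stage as a separately testable function with a
synthetic-claims generator standing in for the restricted billing data.

## Cohort rules

A diagnosis group qualifies a patient when records matching the group's
ICD-10 prefixes and permitted coding qualifiers appear in at least two
distinct quarters of the observation year (**M2Q**, used for chronic
conditions such as hypertension or diabetes) or at least one quarter
(**M1Q**, for acute conditions such as intestinal infections). Qualifier
rules distinguish `confirmed` diagnoses from `status_post` codes following a
hospital stay: acute groups accept confirmed codes only; most chronic groups
accept either; the acute-ischemic sub-rule (I21–I24) accepts `status_post`
only. Two decisions here were genuinely open:

* For M2Q groups accepting both qualifiers, the two qualifying quarters may
  carry *different* qualifiers (one confirmed, one status-post). The rule
  text imposes no same-qualifier constraint, so none is enforced.
* Groups 1 (ischemic heart disease) and 4 (bronchitis/COPD) consist of two
  sub-rules each, evaluated separately; a patient qualifies for the merged
  group if *either* sub-rule is met, matching how the groups are reported.
* ICD prefix matching operates at the printed precision of the catalog: rule
  code `I10` matches `I10.0` and `I10.90`; the one four-digit rule code
  (`R07.0`) matches only codes extending it. Range notation (`I10–I15`,
  `A00–A09`) expands to the inclusive three-character list.
* The minimum patient age defaults to 18 years (the cohort targets adults,
  which is also why pediatricians are excluded); dialysis identification is
  delegated to a patient-level flag because billing data operationalise it
  in carrier-specific ways.

## Edge definition and thresholds

The weight of edge *(i, j)* is the number of **distinct** cohort patients
with at least one qualifying consultation with both physicians. An edge is
retained only if

* `w_ij >= 20` shared patients (a data-protection floor that also removes
  noise edges), and
* `w_ij` amounts to **5% or more** of the panel of at least one of the two
  physicians, where a physician's panel is the number of distinct cohort
  patients they treated in the observation year.

Both comparisons are inclusive (`>=`), reading "5% or more" literally. The
panel denominator is cohort-based, not all-comers: the graph, and therefore
relevance, is defined on the cohort. Pair counting enumerates each patient's
distinct physician set and accumulates the induced pairs, which is
algebraically identical to intersecting all panel pairs but scales with the
number of consultations. A documented consequence of the absolute floor is
that low-volume providers (panels below 20) can never form an edge and end
up isolated; the package flags them rather than dropping them silently.

## Community detection with a size band

Communities are found by maximising weighted Newman–Girvan modularity

$$Q = \frac{1}{2m}\sum_{ij}\left(w_{ij} - \frac{k_i k_j}{2m}\right)\delta(c_i, c_j)$$

with the multilevel (Louvain) algorithm at resolution 1, as implemented in
igraph; the greedy local-moving passes are seeded, so results are
reproducible for a fixed seed. Because the target application (network
meetings) needs groups of 20–120 physicians, the algorithm is applied
**iteratively**: every community larger than 120 is re-partitioned on its
induced subgraph — intra-community edges at their original weights, with no
re-thresholding — until all communities fit the band or cannot be split
further. Three design choices deserve explanation:

* A community the algorithm returns unchanged is *terminal*: it is retained
  even if oversized, and flagged, rather than force-split by a balanced cut.
  The stopping rule is "could not be split further", not "must fit".
* Undersized communities (< 20) are discarded **once, at the end** of the
  recursion, not during it, so that small fragments of an oversized
  community are not lost before that community's own recursion completes.
* Network labels are assigned deterministically (decreasing size, ties by
  smallest member id), so identical inputs give byte-identical outputs.

The suite verifies the optimiser against an exhaustive search over all set
partitions (Bell-number enumeration) on graphs of up to 8 vertices: the
multilevel modularity never exceeds the global optimum and attains it on
clique-pair fixtures.

## Patient allocation

A *treatment day* is a distinct (physician, service date) pair by default:
seeing two physicians of the same practice on one day counts twice, because
the quantity approximates per-physician contacts. A configuration switch
(`day_granularity = "calendar_day"`) collapses this to distinct dates for
sensitivity analyses. The patient is allocated to the network with the most
treatment days only when that count **strictly exceeds 50%** of all the
patient's treatment days — including days with physicians who ended up
isolated or discarded, since responsibility is judged against all care the
patient received. A 50/50 split therefore allocates nobody, and no
tie-breaking is ever needed: at most one network can hold a strict
majority. An independent audit function recomputes every allocated share
from the raw consultation rows.

## Network statistics

Per network, the package reports member counts, allocated patients,
specialty and practice diversity, the patient-averaged share of visits and
of distinct physicians inside the network, and three graph statistics on the
unweighted induced subgraph: degree centrality defined at network level as
*E/V*, edge density *E / (V(V−1)/2)*, and transitivity
*3 × triangles / connected triples*. The within-network proportions are
patient-averaged (each allocated patient contributes one share), with the
pooled variant derivable from the written tables. Associations between the
ten profile columns use Spearman rank correlations (average ranks on ties,
pairwise deletion) with p-values from the *t* approximation
`t = rho * sqrt((n-2)/(1-rho^2))`; the reporting convention flags
significance at the 0.1% level.

## The synthetic-claims generator

Real billing data of this kind are access-restricted, so the package ships a
generator whose defaults emulate the published population structure: 45%
general practitioners among included specialties, practices of 1–4
physicians nested inside planted communities, a mean of 2.5 diagnosis groups
per cohort patient (zero-truncated Poisson, groups drawn by their published
population prevalences), 55% female patients, mean age 54 (SD 16), and four
quarters of consultations with overdispersed per-patient visit counts
(negative binomial, mean 8, size 2 — free parameters, since visit-rate
distributions are not published). Ground truth is expressed through
behaviour: each patient has a home community and directs each visit there
with probability `within_community_visit_prob` (default 0.9), otherwise to a
uniformly chosen other community; larger communities serve proportionally
more patients. Shares of non-cohort patients (15%), dialysis patients (2%),
excluded-specialty physicians (5%) and excluded billing codes (5%) ensure
every filter has work to do.

What the generator does **not** emulate: real referral structure and
geography, specialty-specific visit rates, seasonal patterns, multi-year
continuity, realistic billing-code dictionaries, or practices spanning
communities. Passing recovery tests therefore demonstrates that the
pipeline's machinery is correct under known ground truth — not that any
particular real dataset would yield similar networks.

## Worked example

```{r example}
sim <- generate_bundle(sim_config(seed = 7))
res <- run_pipeline(sim$bundle, pipeline_config(seed = 7))
res
res$profiles[, .(network_id, n_physicians, n_patients,
                 prop_visits_within, density, transitivity)]

# recovery of the planted communities
m <- merge(res$partition$assignment, sim$truth$physician_community,
           by = "physician_id")
mclust::adjustedRandIndex(m$network_id, m$community)
```

## Numerical choices and degenerate inputs

* All randomness flows through R's RNG from a single integer seed; each
  recursion level of the community stage derives its sub-seed
  deterministically from the top-level seed and a run counter.
* Modularity is undefined on a zero-weight graph (error) and partitions of
  edgeless graphs fall back to singletons with a warning.
* Density needs `V >= 2` and transitivity `V >= 3` plus at least one
  connected triple; undefined values propagate as `NA` with warnings, and
  correlations use pairwise deletion.
* Empty cohorts, bundles without diagnoses, and graphs whose communities all
  fall below the minimum size stop the pipeline loudly rather than emitting
  empty files.

## Problem sizes used by the test suite

The suite exercises the pipeline at three scales, chosen as the smallest
sizes at which each property is meaningfully testable: unit fixtures of 2–25
physicians for exact hand-checkable arithmetic; the default generator
conditions (120 physicians in 4 communities, 4,000 patients) for end-to-end
recovery across ten seeds; and a 210-community run (~8,300 physicians,
250,000 patients) to test the qualitative correlation structure across
networks — large networks have more allocated patients and lower edge
density, reproducing the signs reported for real data.

## Known limitations

* The multilevel algorithm is greedy; on adversarial graphs it can return a
  partition below the modularity optimum (never above — the oracle tests
  assert exactly this one-sided guarantee).
* Terminal oversized communities are possible in principle; the partition
  object reports them, and downstream stages treat them like any network.
* The two-region processing of the original application (independent graphs
  per intervention region) is available via `allowed_regions`, but the
  generator plants a single region by default.
* Spearman p-values use the large-sample *t* approximation rather than exact
  permutation distributions; at typical network counts (hundreds) the
  difference is negligible.
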