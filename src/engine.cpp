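#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// uniform integer on {0, ..., n-1} from R's RNG
static inline int ri(int n) {
    int k = (int)(unif_rand() * n);
    return k >= n ? n - 1 : k;
}

// Full run of the per-step scheduler. Semantics match the R-level
// time_step()/replenish() operations exactly (event order i-viii, weight
// computation before baseline mortality, single-shuffle cyclic
// replenishment, degenerate-weight fallbacks); only the order in which
// random numbers are consumed differs. All randomness comes from R's RNG,
// so set.seed() makes a run bit-reproducible.
// [[Rcpp::export]]
List run_engine_cpp(int n_agents, int n_steps, int n_options,
                    int reward_min, int reward_max, double p_change,
                    int danger_count, double p_danger, double p_newdanger,
                    double alpha, double fatal_r, double q_init,
                    double mut_event_prob, double eps_range,
                    bool prep_enabled, double baseline_death_prob,
                    int pure_o, int pure_t, bool lock_strategy,
                    int record_every) {
    const int no = n_options;
    const int span = reward_max - reward_min + 1;

    std::vector<double> prep((size_t)n_agents * no, 0.0);
    std::vector<double> q((size_t)n_agents * no, q_init);
    std::vector<double> f(n_agents, 0.0), w(n_agents, 0.0);
    std::vector<int> obs(n_agents, pure_o), par(n_agents, pure_t);
    std::vector<int> age(n_agents, 0);
    std::vector<char> alive(n_agents, 1);

    std::vector<int> rewards(no);
    std::vector<char> dang(no, 0);
    for (int j = 0; j < no; ++j) rewards[j] = reward_min + ri(span);
    {   // danger_count distinct options, uniform, independent of rewards
        std::vector<int> idx(no);
        for (int j = 0; j < no; ++j) idx[j] = j;
        for (int k = 0; k < danger_count; ++k) {
            int j = k + ri(no - k);
            std::swap(idx[k], idx[j]);
            dang[idx[k]] = 1;
        }
    }

    const int max_rec = (record_every > 0 ? n_steps / record_every : 0) + 2;
    NumericMatrix rec(max_rec, 11);
    int n_rec = 0;
    bool collapsed = false;

    std::vector<int> choice(n_agents, -1);
    std::vector<double> rew(n_agents, 0.0);
    std::vector<char> fatal(n_agents, 0);
    std::vector<int> actors, surv, freeslot;
    actors.reserve(n_agents);
    surv.reserve(n_agents);
    freeslot.reserve(n_agents);
    std::vector<double> cw(no);

    for (int t = 1; t <= n_steps; ++t) {
        if (t % 4096 == 0) Rcpp::checkUserInterrupt();

        // (i) reward drift: at most one option redrawn per step
        if (p_change > 0 && unif_rand() < p_change) {
            int o = ri(no);
            rewards[o] = reward_min + ri(span);
        }
        // (i') novel dangers: sequential reassignment, each dangerous
        // option replaced by a uniform draw from the currently safe ones
        if (p_newdanger > 0 && danger_count > 0 &&
            unif_rand() < p_newdanger) {
            std::vector<int> ds;
            for (int j = 0; j < no; ++j) if (dang[j]) ds.push_back(j);
            for (size_t k = 0; k < ds.size(); ++k) {
                int d = ds[k];
                dang[d] = 0;
                int ncand = 0;
                for (int j = 0; j < no; ++j)
                    if (!dang[j] && j != d) ++ncand;
                int r = ri(ncand);
                for (int j = 0; j < no; ++j) {
                    if (!dang[j] && j != d) {
                        if (r == 0) { dang[j] = 1; break; }
                        --r;
                    }
                }
            }
        }

        // (ii) softmax choice over Q + P (max-shifted) and outcome
        actors.clear();
        for (int i = 0; i < n_agents; ++i) {
            if (!alive[i]) continue;
            actors.push_back(i);
            const double *qi = &q[(size_t)i * no];
            const double *pi = &prep[(size_t)i * no];
            double m = qi[0] + pi[0];
            for (int j = 1; j < no; ++j) {
                double v = qi[j] + pi[j];
                if (v > m) m = v;
            }
            double s = 0.0;
            for (int j = 0; j < no; ++j) {
                s += std::exp(qi[j] + pi[j] - m);
                cw[j] = s;
            }
            double u = unif_rand() * s;
            int c = no - 1;
            for (int j = 0; j < no; ++j)
                if (u <= cw[j]) { c = j; break; }
            choice[i] = c;
            rew[i] = rewards[c];
            fatal[i] = (dang[c] && unif_rand() < p_danger) ? 1 : 0;
        }
        const int na = (int)actors.size();

        // (iii) observational learning from one other actor, fatalities
        // visible (vicarious reinforcement fatal_r)
        if (na > 1) {
            for (int a = 0; a < na; ++a) {
                int i = actors[a];
                if (!obs[i]) continue;
                int k = ri(na - 1);
                if (k >= a) ++k;
                int tgt = actors[k];
                double R = fatal[tgt] ? fatal_r : rew[tgt];
                double *qi = &q[(size_t)i * no];
                int c = choice[tgt];
                qi[c] += alpha * (R - qi[c]);
            }
        }

        // (iv) fatal removals: dying agents get no own update, no reward
        int danger_deaths = 0;
        for (int a = 0; a < na; ++a) {
            int i = actors[a];
            if (fatal[i]) { alive[i] = 0; ++danger_deaths; }
        }

        // (v) survivors update own option and bank the reward
        for (int a = 0; a < na; ++a) {
            int i = actors[a];
            if (!alive[i]) continue;
            double *qi = &q[(size_t)i * no];
            int c = choice[i];
            qi[c] += alpha * (rew[i] - qi[c]);
            f[i] += rew[i];
            ++age[i];
        }

        // (vi) reproduction weights: f_i / max f (all equal if max f = 0)
        surv.clear();
        double maxf = 0.0;
        for (int i = 0; i < n_agents; ++i)
            if (alive[i]) {
                surv.push_back(i);
                if (f[i] > maxf) maxf = f[i];
            }
        for (size_t k = 0; k < surv.size(); ++k) {
            int i = surv[k];
            w[i] = (maxf > 0.0) ? f[i] / maxf : 1.0;
        }

        // (vii) baseline mortality; weights not recomputed
        int baseline_deaths = 0;
        for (size_t k = 0; k < surv.size(); ++k) {
            int i = surv[k];
            if (unif_rand() < baseline_death_prob) {
                alive[i] = 0;
                ++baseline_deaths;
            }
        }

        // (viii) replenish: one shuffle, cyclic Bernoulli visits
        surv.clear();
        freeslot.clear();
        for (int i = 0; i < n_agents; ++i) {
            if (alive[i]) surv.push_back(i);
            else freeslot.push_back(i);
        }
        if (surv.empty()) { collapsed = true; break; }
        int births = 0;
        int vac = (int)freeslot.size();
        if (vac > 0) {
            const int ns = (int)surv.size();
            for (int k = ns - 1; k > 0; --k) {
                int j = ri(k + 1);
                std::swap(surv[k], surv[j]);
            }
            double wmax = 0.0;
            for (int k = 0; k < ns; ++k)
                if (w[surv[k]] > wmax) wmax = w[surv[k]];
            const bool equalw = (wmax <= 0.0);
            int pos = 0;
            while (vac > 0) {
                int p = surv[pos];
                pos = (pos + 1) % ns;
                double wp = equalw ? 1.0 : w[p];
                if (unif_rand() < wp) {
                    int slot = freeslot[births];
                    double *pd = &prep[(size_t)slot * no];
                    const double *ps = &prep[(size_t)p * no];
                    for (int j = 0; j < no; ++j) pd[j] = ps[j];
                    obs[slot] = obs[p];
                    par[slot] = par[p];
                    if (unif_rand() < mut_event_prob) {
                        int locus = ri(no + 2);
                        if (locus < no) {
                            if (prep_enabled)
                                pd[locus] += (2.0 * unif_rand() - 1.0) * eps_range;
                        } else if (locus == no) {
                            if (!lock_strategy) obs[slot] = 1 - obs[slot];
                        } else {
                            if (!lock_strategy) par[slot] = 1 - par[slot];
                        }
                    }
                    double *qd = &q[(size_t)slot * no];
                    if (par[slot] == 1) {
                        const double *qs = &q[(size_t)p * no];
                        for (int j = 0; j < no; ++j) qd[j] = qs[j];
                    } else {
                        for (int j = 0; j < no; ++j) qd[j] = q_init;
                    }
                    f[slot] = 0.0;
                    age[slot] = 0;
                    alive[slot] = 1;
                    ++births;
                    --vac;
                }
            }
        }

        if (t % record_every == 0 || t == n_steps) {
            int cnt[4] = {0, 0, 0, 0};
            double sumf = 0.0;
            double pmax = R_NegInf, pmin = R_PosInf;
            int nalive = 0;
            for (int i = 0; i < n_agents; ++i) {
                if (!alive[i]) continue;
                ++nalive;
                cnt[obs[i] + 2 * par[i]] += 1;
                sumf += f[i];
                const double *pi = &prep[(size_t)i * no];
                for (int j = 0; j < no; ++j) {
                    if (pi[j] > pmax) pmax = pi[j];
                    if (pi[j] < pmin) pmin = pi[j];
                }
            }
            rec(n_rec, 0) = t;
            rec(n_rec, 1) = cnt[0];
            rec(n_rec, 2) = cnt[1];
            rec(n_rec, 3) = cnt[2];
            rec(n_rec, 4) = cnt[3];
            rec(n_rec, 5) = sumf / nalive;
            rec(n_rec, 6) = danger_deaths;
            rec(n_rec, 7) = baseline_deaths;
            rec(n_rec, 8) = births;
            rec(n_rec, 9) = pmax;
            rec(n_rec, 10) = pmin;
            ++n_rec;
        }
    }

    NumericMatrix records(n_rec, 11);
    for (int r = 0; r < n_rec; ++r)
        for (int cidx = 0; cidx < 11; ++cidx)
            records(r, cidx) = rec(r, cidx);

    NumericMatrix prep_m(n_agents, no), q_m(n_agents, no);
    for (int i = 0; i < n_agents; ++i)
        for (int j = 0; j < no; ++j) {
            prep_m(i, j) = prep[(size_t)i * no + j];
            q_m(i, j) = q[(size_t)i * no + j];
        }
    IntegerVector obs_v(obs.begin(), obs.end());
    IntegerVector par_v(par.begin(), par.end());
    IntegerVector age_v(age.begin(), age.end());
    NumericVector f_v(f.begin(), f.end());
    LogicalVector alive_v(n_agents);
    for (int i = 0; i < n_agents; ++i) alive_v[i] = (alive[i] != 0);

    return List::create(
        _["records"] = records,
        _["preparedness"] = prep_m,
        _["q_values"] = q_m,
        _["obs_allele"] = obs_v,
        _["par_allele"] = par_v,
        _["f"] = f_v,
        _["age"] = age_v,
        _["alive"] = alive_v,
        _["collapsed"] = collapsed);
}
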