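protocol:
- stage_id: Habituation1
  target_sequence: []
  windows: []
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 10.0
  reward_cap: 40.0
  reinforced: yes
  schedule:
    delivery_interval_s: ~
    n_deliveries: 0
    preloaded_pellets: 0
  criteria:
    type: none
    reward_target: ~
    consecutive_days: 1
    max_sessions: ~
    last_session_min_trials: ~
    fixed_sessions: 1
    force_advance: no
- stage_id: Habituation2
  target_sequence: []
  windows: []
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 10.0
  reward_cap: 40.0
  reinforced: yes
  schedule:
    delivery_interval_s: ~
    n_deliveries: 0
    preloaded_pellets: 4
  criteria:
    type: rewards
    reward_target: 4.0
    consecutive_days: 1
    max_sessions: 10
    last_session_min_trials: ~
    fixed_sessions: ~
    force_advance: no
- stage_id: Habituation3
  target_sequence: []
  windows: []
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 30.0
  reward_cap: 15.0
  reinforced: yes
  schedule:
    delivery_interval_s: 120.0
    n_deliveries: 15
    preloaded_pellets: 0
  criteria:
    type: rewards
    reward_target: 15.0
    consecutive_days: 1
    max_sessions: 10
    last_session_min_trials: ~
    fixed_sessions: ~
    force_advance: no
- stage_id: OperantTraining
  target_sequence:
  - L
  windows: []
  any_lever: yes
  timeout_s: 5.0
  session_cap_min: 30.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 1
    max_sessions: 10
    last_session_min_trials: ~
    fixed_sessions: ~
    force_advance: no
- stage_id: LR
  target_sequence:
  - L
  - R
  windows:
  - low: 0.05
    high: 3600.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 3
    max_sessions: 10
    last_session_min_trials: ~
    fixed_sessions: ~
    force_advance: no
- stage_id: LLR
  target_sequence:
  - L
  - L
  - R
  windows:
  - low: 0.05
    high: 3600.0
  - low: 0.05
    high: 3600.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 3
    max_sessions: 10
    last_session_min_trials: ~
    fixed_sessions: ~
    force_advance: no
- stage_id: LLRR
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.05
    high: 3600.0
  - low: 0.05
    high: 3600.0
  - low: 0.05
    high: 3600.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 3
    max_sessions: 10
    last_session_min_trials: ~
    fixed_sessions: ~
    force_advance: no
- stage_id: LLRR_baseline
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 3
    max_sessions: 10
    last_session_min_trials: 10
    fixed_sessions: ~
    force_advance: yes
- stage_id: LLRR_strict
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 2.0
  - low: 0.5
    high: 10.0
  - low: 0.5
    high: 2.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 3
    max_sessions: 10
    last_session_min_trials: 10
    fixed_sessions: ~
    force_advance: yes
- stage_id: LLRR_alternating
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  alternation:
    period: 4
    alternate_sequence:
    - L
    - L
    - R
  criteria:
    type: none
    reward_target: ~
    consecutive_days: 1
    max_sessions: ~
    last_session_min_trials: ~
    fixed_sessions: 3
    force_advance: no
- stage_id: LLRR_rebaseline
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 1
    max_sessions: 3
    last_session_min_trials: 10
    fixed_sessions: ~
    force_advance: yes
- stage_id: LLRR_LEFT
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 1.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: none
    reward_target: ~
    consecutive_days: 1
    max_sessions: ~
    last_session_min_trials: ~
    fixed_sessions: 3
    force_advance: no
- stage_id: LLRR_rebaseline
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 1
    max_sessions: 3
    last_session_min_trials: 10
    fixed_sessions: ~
    force_advance: yes
- stage_id: LLRR_RIGHT
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 1.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: none
    reward_target: ~
    consecutive_days: 1
    max_sessions: ~
    last_session_min_trials: ~
    fixed_sessions: 3
    force_advance: no
- stage_id: LLRR_rebaseline
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 1
    max_sessions: 3
    last_session_min_trials: 10
    fixed_sessions: ~
    force_advance: yes
- stage_id: LLRR_MIDDLE
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 3.0
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: none
    reward_target: ~
    consecutive_days: 1
    max_sessions: ~
    last_session_min_trials: ~
    fixed_sessions: 3
    force_advance: no
- stage_id: LLRR_rebaseline
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  reinforced: yes
  criteria:
    type: rewards
    reward_target: 40.0
    consecutive_days: 1
    max_sessions: 3
    last_session_min_trials: 10
    fixed_sessions: ~
    force_advance: yes
- stage_id: Extinction
  target_sequence:
  - L
  - L
  - R
  - R
  windows:
  - low: 0.5
    high: 5.0
  - low: 0.5
    high: 20.0
  - low: 0.5
    high: 5.0
  any_lever: no
  timeout_s: 5.0
  session_cap_min: 60.0
  reward_cap: 40.0
  trial_cap: 40.0
  reinforced: no
  criteria:
    type: none
    reward_target: ~
    consecutive_days: 1
    max_sessions: ~
    last_session_min_trials: ~
    fixed_sessions: 1
    force_advance: no

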