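participant,day,session,fatigue_level,au,crt_pre_mean,crt_pre_sd,crt_pre_errors,crt_post_mean,crt_post_sd,crt_post_errors,vasf_fatigue,vasf_energy
1,1,1,0,2.64686097824807,0.294255789949684,0.0417947946073917,0,0.370226246435382,0.0592964222159424,1,1.43525538398181,8.01341756368096
1,1,2,0.6,0.970255662302517,0.374434000943495,0.0689541986264316,7,0.387241492426517,0.0926117026611351,3,5.07218336651658,4.17315417451417
2,1,1,0,3.17244094542122,0.332089966114591,0.0601523787705342,1,0.336853338213791,0.04873730784208,1,0.308206773956537,8.1830574177037
2,1,2,0.6,1.02890809678411,0.377809041782768,0.0586608366152358,3,0.402537371849513,0.0632711285215126,4,6.92819241663071,3.90181833894669
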