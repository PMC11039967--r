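name value init_std min max
st1_KC_ilpso 0.251562686358172 0.1 0 1
st1_KL_ilpso 0 0.5 0 5
st1_LO_ilpso 0.96074201566469 0.1 0.5 1.5
st1_KFp_ilpso 0 0.5 0 5
st1_KFm_ilpso 1.14440724621298 0.5 0 5
st1_KC_gmax 0.0678884828174696 0.1 0 1
st1_KL_gmax 0.186028201339772 0.5 0 5
st1_LO_gmax 0.833884686262983 0.1 0.5 1.5
st1_KFp_gmax 0 0.5 0 5
st1_KFm_gmax 2.03859087491636 0.5 0 5
st1_KC_adm 0 0.1 0 1
st1_KL_adm 0 0.5 0 5
st1_LO_adm 1.00664865657455 0.1 0.5 1.5
st1_KFp_adm 0 0.5 0 5
st1_KFm_adm 0 0.5 0 5
st1_KC_rf 0.202589926159566 0.1 0 1
st1_KL_rf 0.720721500095613 0.5 0 5
st1_LO_rf 0.993746779567261 0.1 0.5 1.5
st1_KFp_rf 0 0.5 0 5
st1_KFm_rf 0.278424096122293 0.5 0 5
st1_KC_vas 0 0.1 0 1
st1_KL_vas 0 0.5 0 5
st1_LO_vas 1.08115070374114 0.1 0.5 1.5
st1_KFp_vas 0 0.5 0 5
st1_KFm_vas 0 0.5 0 5
st1_KC_ham 0.0724223557287912 0.1 0 1
st1_KL_ham 0.17329262927362 0.5 0 5
st1_LO_ham 1.18845545271603 0.1 0.5 1.5
st1_KFp_ham 0 0.5 0 5
st1_KFm_ham 1.42951184426736 0.5 0 5
st1_KC_bfsh 0.0748114349767577 0.1 0 1
st1_KL_bfsh 1.1795010938322 0.5 0 5
st1_LO_bfsh 1.00739003667695 0.1 0.5 1.5
st1_KFp_bfsh 0 0.5 0 5
st1_KFm_bfsh 0.270211009383584 0.5 0 5
st1_KC_gas 0.0680023701040599 0.1 0 1
st1_KL_gas 0 0.5 0 5
st1_LO_gas 0.914066077419381 0.1 0.5 1.5
st1_KFp_gas 0 0.5 0 5
st1_KFm_gas 0.197491179119669 0.5 0 5
st1_KC_sol 0 0.1 0 1
st1_KL_sol 0.664138380425193 0.5 0 5
st1_LO_sol 0.963452747330171 0.1 0.5 1.5
st1_KFp_sol 0 0.5 0 5
st1_KFm_sol 0 0.5 0 5
st1_KC_ta 0.110804431175514 0.1 0 1
st1_KL_ta 0 0.5 0 5
st1_LO_ta 1.02638745402816 0.1 0.5 1.5
st1_KFp_ta 0.170123980981273 0.5 0 5
st1_KFm_ta 0.300580571295424 0.5 0 5
st1_KP_ilpso -0.319161820407912 1 -5 5
st1_KV_ilpso 0.0853292742111535 0.4 -2 2
st1_KP_gmax -0.199910354640859 1 -5 5
st1_KV_gmax 0.256962267393746 0.4 -2 2
st1_KP_adm -1.41058734595756 1 -5 5
st1_KV_adm -0.455035636437505 0.4 -2 2
st1_KP_ham 1.34169311463994 1 -5 5
st1_KV_ham 0.444031493924783 0.4 -2 2
st1_KP_sol -2.2929890752306 1 -5 5
st1_KV_sol 0.223342744794938 0.4 -2 2
st1_KP_ta 0.607585213397312 1 -5 5
st1_KV_ta -0.349445903518381 0.4 -2 2
st1_theta0 0.310073755652281 0.15 -0.5 1
st1_trunk_lum_q0 0.711638383512271 0.08727 0 0.8727
st1_trunk_lum_kp 112.412472449287 50 0 500
st1_trunk_lum_kv 23.7828198076453 5 0 50
st1_trunk_th_q0 0.2618 0.05236 -0.2618 0.2618
st1_trunk_th_kp 142.344824448185 50 0 500
st1_trunk_th_kv 15.7169024281048 5 0 50
st2_KC_ilpso 0.0700958898567207 0.1 0 1
st2_KL_ilpso 0 0.5 0 5
st2_LO_ilpso 0.954518922546797 0.1 0.5 1.5
st2_KFp_ilpso 0.326291399761766 0.5 0 5
st2_KFm_ilpso 0.221807538419462 0.5 0 5
st2_KC_gmax 0.281642694852801 0.1 0 1
st2_KL_gmax 0.859813574828852 0.5 0 5
st2_LO_gmax 1.02171684888711 0.1 0.5 1.5
st2_KFp_gmax 0 0.5 0 5
st2_KFm_gmax 0.698436117143019 0.5 0 5
st2_KC_adm 0.151489163351043 0.1 0 1
st2_KL_adm 0.305794295950563 0.5 0 5
st2_LO_adm 0.799917674338702 0.1 0.5 1.5
st2_KFp_adm 0 0.5 0 5
st2_KFm_adm 0.614740841691829 0.5 0 5
st2_KC_rf 0.126214765117943 0.1 0 1
st2_KL_rf 0.134389129688937 0.5 0 5
st2_LO_rf 0.870398946773812 0.1 0.5 1.5
st2_KFp_rf 0.061499224942722 0.5 0 5
st2_KFm_rf 0 0.5 0 5
st2_KC_vas 0.381067197358008 0.1 0 1
st2_KL_vas 0 0.5 0 5
st2_LO_vas 0.912221081703182 0.1 0.5 1.5
st2_KFp_vas 1.81343286938771 0.5 0 5
st2_KFm_vas 0.486414133096975 0.5 0 5
st2_KC_ham 0.257790742025308 0.1 0 1
st2_KL_ham 0.206562485756469 0.5 0 5
st2_LO_ham 0.933139585471049 0.1 0.5 1.5
st2_KFp_ham 0.266626613158271 0.5 0 5
st2_KFm_ham 0 0.5 0 5
st2_KC_bfsh 0.0269841060772601 0.1 0 1
st2_KL_bfsh 0.309377688770661 0.5 0 5
st2_LO_bfsh 1.10176614303764 0.1 0.5 1.5
st2_KFp_bfsh 1.05968220998695 0.5 0 5
st2_KFm_bfsh 0.233997449607127 0.5 0 5
st2_KC_gas 0.00619213949272354 0.1 0 1
st2_KL_gas 0.306065216967021 0.5 0 5
st2_LO_gas 0.810307393967774 0.1 0.5 1.5
st2_KFp_gas 0.213259547297297 0.5 0 5
st2_KFm_gas 0 0.5 0 5
st2_KC_sol 0.141815761998003 0.1 0 1
st2_KL_sol 0.0705750110917902 0.5 0 5
st2_LO_sol 0.948652105475117 0.1 0.5 1.5
st2_KFp_sol 0.0953212361577546 0.5 0 5
st2_KFm_sol 0.611457849175076 0.5 0 5
st2_KC_ta 0.510361893613219 0.1 0 1
st2_KL_ta 0.193598513577308 0.5 0 5
st2_LO_ta 1.16795244241024 0.1 0.5 1.5
st2_KFp_ta 0 0.5 0 5
st2_KFm_ta 0 0.5 0 5
st2_KP_ilpso -1.01728989657455 1 -5 5
st2_KV_ilpso -0.422374426973636 0.4 -2 2
st2_KP_gmax 2.46915991080088 1 -5 5
st2_KV_gmax 0.744529387000743 0.4 -2 2
st2_KP_adm 2.74623685161541 1 -5 5
st2_KV_adm 0.132211727642677 0.4 -2 2
st2_KP_ham 2.98332233205608 1 -5 5
st2_KV_ham -0.692858750338775 0.4 -2 2
st2_KP_sol 2.95964459251657 1 -5 5
st2_KV_sol 1.1670302965968 0.4 -2 2
st2_KP_ta -2.646006286752 1 -5 5
st2_KV_ta -1.38791176815317 0.4 -2 2
st2_theta0 0.213296208766896 0.15 -0.5 1
st2_trunk_lum_q0 0.348389545518659 0.08727 0 0.8727
st2_trunk_lum_kp 319.107075610216 50 0 500
st2_trunk_lum_kv 9.57052471435784 5 0 50
st2_trunk_th_q0 0.09013813862388 0.05236 -0.2618 0.2618
st2_trunk_th_kp 222.067290571594 50 0 500
st2_trunk_th_kv 19.6966423268536 5 0 50
sched_t_state2 0.436546117351636 0.09 0.1 1
sched_t_gait 1.84135637611612 0.2 0.5 2.5
sched_stance_thr 0.25980940503696 0.055 0.05 0.6
gait_C_SOL 0.02 0.1 0 1
gait_G_SOL_F 1 0.5 0 5
gait_C_GAS 0.02 0.1 0 1
gait_G_GAS_F 1 0.5 0 5
gait_C_GAS_PUSH 0.2 0.1 0 1
gait_C_TA 0.05 0.1 0 1
gait_G_TA_L 1.5 0.5 0 5
gait_LO_TA_G 1 0.1 0.5 1.5
gait_G_TA_FSOL 0.4 0.5 0 5
gait_C_VAS_G 0.08 0.1 0 1
gait_G_VAS_F 1 0.5 0 5
gait_S_VAS_LO 0.3 0.1 0 1
gait_C_VAS_LD 0.15 0.1 0 1
gait_K_KO 2 1 0 10
gait_C_GMAX_G 0.05 0.1 0 1
gait_G_GMAX_P 1.5 1 -5 5
gait_G_GMAX_V 0.3 0.4 -2 2
gait_C_GMAX_SW 0.02 0.1 0 1
gait_C_GMAX_LD 0.1 0.1 0 1
gait_C_ADM_G 0.03 0.1 0 1
gait_C_HAM_G 0.04 0.1 0 1
gait_G_HAM_P 1 1 -5 5
gait_G_HAM_V 0.2 0.4 -2 2
gait_G_HAM_SWF 0.3 0.5 0 5
gait_G_HAM_SWL 1 0.5 0 5
gait_LO_HAM_SW 0.95 0.1 0.5 1.5
gait_C_HAM_LD 0.1 0.1 0 1
gait_C_ILP_ST 0.02 0.1 0 1
gait_G_ILP_P 1 1 -5 5
gait_G_ILP_V 0.2 0.4 -2 2
gait_C_ILP_PUSH 0.15 0.1 0 1
gait_C_ILP_LF 0.35 0.1 0 1
gait_C_ILP_SW 0.2 0.1 0 1
gait_G_ILP_L 1 0.5 0 5
gait_LO_ILP 0.9 0.1 0.5 1.5
gait_C_BFSH_LF 0.25 0.1 0 1
gait_C_RF_ST 0.02 0.1 0 1
gait_C_RF_SW 0.05 0.1 0 1
gait_THETA0_G 0.08 0.08 -0.3 0.5
gait_HIP_SW_THR 0.5 0.12 0 1.2
gait_TR_L_Q0 0.1 0.08727 0 0.8727
gait_TR_L_KP 150 50 0 500
gait_TR_L_KV 10 5 0 50
gait_TR_T_Q0 0.05 0.05236 -0.2618 0.2618
gait_TR_T_KP 100 50 0 500
gait_TR_T_KV 8 5 0 50
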