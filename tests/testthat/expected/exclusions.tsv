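kind	id	reason
cnv_qc	ALPHA_case_00006:S01:5168334-5408799	length <= 250000 bp
cnv_qc	ALPHA_case_00022:S02:2329581-2541005	length <= 250000 bp
cnv_qc	ALPHA_case_00031:S03:120368-320689	length <= 250000 bp
cnv_qc	ALPHA_case_00034:S01:558198-801927	length <= 250000 bp
cnv_qc	ALPHA_case_00045:S02:1149520-1350971	length <= 250000 bp
cnv_qc	ALPHA_case_00050:S02:5283025-5490822	length <= 250000 bp
cnv_qc	ALPHA_case_00057:S03:165173-368791	length <= 250000 bp
cnv_qc	ALPHA_control_00008:S01:969011-1211971	length <= 250000 bp
cnv_qc	ALPHA_control_00011:S03:3537752-3764838	length <= 250000 bp
cnv_qc	ALPHA_control_00011:S03:4700681-4918022	length <= 250000 bp
cnv_qc	ALPHA_control_00018:S01:4647574-4871799	length <= 250000 bp
cnv_qc	ALPHA_control_00048:S02:4735228-4945523	length <= 250000 bp
cnv_qc	ALPHA_control_00054:S01:4714984-4941088	length <= 250000 bp
cnv_qc	ALPHA_control_00066:S02:2251558-2491210	length <= 250000 bp
cnv_qc	ALPHA_control_00074:S01:2480839-2720963	length <= 250000 bp
cnv_qc	ALPHA_control_00078:S03:4764605-4986163	length <= 250000 bp
cnv_qc	BETA_case_00018:S03:3379169-3597841	length <= 250000 bp
cnv_qc	BETA_case_00029:S01:1843128-2063953	length <= 250000 bp
cnv_qc	BETA_case_00046:S02:1412433-1652398	length <= 250000 bp
cnv_qc	BETA_case_00049:S02:1132981-1337647	length <= 250000 bp
cnv_qc	BETA_case_00076:S03:2781400-3008222	length <= 250000 bp
cnv_qc	BETA_control_00028:S02:1917418-2143884	length <= 250000 bp
cnv_qc	BETA_control_00030:S03:2681134-2889917	length <= 250000 bp
cnv_qc	BETA_control_00066:S01:3118003-3350984	length <= 250000 bp
cnv_qc	BETA_control_00078:S03:4241112-4473610	length <= 250000 bp
cnv_qc	GAMMA_case_00006:S03:2705723-2939920	length <= 250000 bp
cnv_qc	GAMMA_case_00020:S03:5687248-5926006	length <= 250000 bp
cnv_qc	GAMMA_case_00027:S01:2425584-2645331	length <= 250000 bp
cnv_qc	GAMMA_case_00047:S02:1952302-2195018	length <= 250000 bp
cnv_qc	GAMMA_control_00005:S01:4033262-4243316	length <= 250000 bp
cnv_qc	GAMMA_control_00010:S03:5090459-5333523	length <= 250000 bp
cnv_qc	ALPHA_control_00026:S01:123472-492342	mask overlap > 0.5 of length
cnv_qc	BETA_case_00058:S01:169330-595846	mask overlap > 0.5 of length
cnv_qc	GAMMA_case_00048:S01:4476688-4784893	mask overlap > 0.5 of length
cnv_qc	GAMMA_control_00055:S01:4335256-4746598	mask overlap > 0.5 of length
screen_set	TINY	set size 2 outside [3, 1500]
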