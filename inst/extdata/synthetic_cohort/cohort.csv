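"node_diameter_src","cortical_thickness_src","hilum_src","grade_src","tumor_size_src","er_status_src","outcome_src"
"14.60294536","2.113307047","2","2","24.1059599","2","1"
"6.601546188","5.310699616","1","2","22.88336952","1","0"
"12.69619058","2.113404608","1","1","31.56610897","1","0"
"11.57625608","1.631825828","2","2","","1","0"
"8.666801924","3.43370249","1","2","21.96390647","1","0"
"-0.58044516","4.519031795","1","2","21.830276","2","0"
"8.324266013","3.486683933","2","2","23.10801386","2","0"
"6.899388684","2.587623402","1","2","13.43898344","1","0"
"12.56777221","4.910959102","1","2","31.88849654","2","1"
"9.631045091","6.397339651","2","1","17.68151924","1","0"
"9.958926478","1.149784678","","3","19.63016868","2","0"
"8.347833607","5.268307872","2","2","","1","0"
"10.892817","2.930139246","2","2","18.80794157","2","0"
"10.87091738","4.677405181","2","1","21.17212118","1","0"
"-0.7344072306","1.310773737","1","2","34.23627232","1","0"
"18.7350075","3.187267019","2","2","16.92290833","1","1"
"15.08204073","2.349385625","1","2","20.18516329","1","0"
"13.08782169","2.911645148","","2","34.00867274","1","0"
"7.976405848","2.207243944","","3","19.26029214","2","0"
"15.44873389","3.943311093","1","2","17.57017955","2","0"
"10.35663993","4.959519777","1","2","24.06101497","1","0"
"11.17659212","2.907388117","1","2","26.90497407","1","0"
"5.039855601","3.226658335","1","1","16.78170107","1","0"
"19.32912381","2.166021336","1","2","20.89375177","1","0"
"12.24103404","4.694999707","2","2","21.01089599","1","1"
"21.54041917","4.174194669","1","2","14.28235827","1","0"
"20.65472264","1.622865732","1","2","22.15234547","1","0"
"12.29072919","5.277292423","1","2","35.53353883","2","1"
"15.22664081","2.09695382","1","2","29.08647257","1","1"
"20.62814493","2.237583755","1","1","16.16055884","2","1"
"9.355165413","1.73378537","1","1","24.81507746","1","0"
"12.83196013","2.067875695","2","2","20.02135285","2","0"
"10.72638213","3.08242469","1","1","20.69126535","1","0"
"13.6639118","4.139387052","1","2","28.97888448","1","0"
"12.91216406","2.646813709","1","3","26.84750571","1","0"
"17.82296875","3.261213035","2","2","29.4179265","2","1"
"14.96746425","3.162352012","2","3","25.66435549","1","0"
"7.541101354","4.90511153","1","2","15.59108781","2","0"
"14.88626655","6.246479823","1","3","18.02301478","1","1"
"7.875472095","2.217372063","2","2","12.29625748","2","0"
"6.213730712","5.787445026","1","1","26.95770079","1","0"
"15.88999387","6.058157262","1","2","32.87730606","1","0"
"5.97889107","3.777747636","2","2","9.031481898","1","0"
"13.53357051","4.576334885","1","2","22.63647599","1","1"
"7.831707297","1.413448745","1","2","26.1007451","2","0"
"19.09070582","4.062617528","1","1","20.24718449","1","0"
"15.55893059","2.847022792","","2","15.39249044","1","0"
"9.987511386","3.301503015","2","1","13.89137405","1","1"
"15.99681109","4.162599875","1","2","32.25652997","1","0"
"14.13242218","4.739996254","2","2","20.30284401","1","0"
"6.15050665","3.444585434","2","3","31.47901789","2","0"
"10.9689992","6.666448775","","1","16.79510051","1","1"
"7.346948454","4.206806899","2","2","","1","1"
"14.24698783","3.257147199","1","1","26.31146573","1","0"
"8.775967727","4.029872166","","2","22.20432443","2","0"
"10.84288655","3.379690758","1","2","31.31158026","1","0"
"5.818159943","2.18791521","1","1","19.05899414","1","0"
"7.195223509","4.103896806","1","1","19.09304344","1","0"
"12.66978141","4.639088109","1","1","21.94597308","1","0"
"7.004736385","3.959362467","1","3","21.19622001","1","0"
"11.29264655","3.945893853","2","2","20.81126337","2","0"
"12.8366495","3.688659682","2","3","20.53637796","1","1"
"11.00605694","4.517527868","1","1","","1","1"
"10.54396406","1.959928812","1","2","29.66527346","1","0"
"3.328014829","4.88993433","2","1","15.28738447","2","0"
"10.63635834","2.409072544","1","2","15.92220577","1","0"
"3.000352592","3.901988846","1","1","15.06788144","1","0"
"17.76370488","4.431024898","1","2","35.27220535","1","0"
"6.983402572","3.784568183","1","2","","1","0"
"12.74105022","1.628155838","1","1","26.81108904","1","0"
"14.5974834","3.529192101","","1","6.241705431","1","0"
"12.02718147","3.901562227","2","2","18.95913801","1","0"
"18.73510417","4.687293199","1","2","31.26218835","1","1"
"7.764832914","4.100450136","1","2","","1","0"
"14.21699009","4.192289439","","1","5.907932602","1","0"
"7.114252658","4.871229128","1","3","","2","0"
"22.62245568","2.651062623","","1","11.05232184","1","1"
"15.4384948","2.757728431","2","2","11.01524592","1","0"
"10.2831589","3.490022965","1","3","27.8991084","1","0"
"15.92584736","3.906703681","1","1","25.63767473","1","0"
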