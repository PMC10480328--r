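vault,technique,width_deg,bin_deg,percent
A-1,3D-CRT,90,0,17.1
A-1,3D-CRT,90,90,21.2
A-1,3D-CRT,90,180,28.5
A-1,3D-CRT,90,270,33.2
A-1,VMAT,90,0,25.9
A-1,VMAT,90,90,24.8
A-1,VMAT,90,180,22.5
A-1,VMAT,90,270,26.8
A-1,Total,90,0,25.1
A-1,Total,90,90,24.7
A-1,Total,90,180,23.6
A-1,Total,90,270,26.6
A-2,3D-CRT,90,0,33.4
A-2,3D-CRT,90,90,18.9
A-2,3D-CRT,90,180,27.4
A-2,3D-CRT,90,270,20.3
A-2,VMAT,90,0,25.9
A-2,VMAT,90,90,25.6
A-2,VMAT,90,180,19.4
A-2,VMAT,90,270,29.1
A-2,Total,90,0,26.3
A-2,Total,90,90,24.8
A-2,Total,90,180,20.4
A-2,Total,90,270,28.5
B,3D-CRT,90,0,32.2
B,3D-CRT,90,90,16.6
B,3D-CRT,90,180,31.2
B,3D-CRT,90,270,20
B,IMRT,90,0,28.9
B,IMRT,90,90,25.3
B,IMRT,90,180,21.6
B,IMRT,90,270,24.2
B,VMAT,90,0,27.2
B,VMAT,90,90,24.3
B,VMAT,90,180,24.3
B,VMAT,90,270,24.2
B,Total,90,0,28.1
B,Total,90,90,24.3
B,Total,90,180,23.5
B,Total,90,270,24.1
C,3D-CRT,90,0,24.2
C,3D-CRT,90,90,34.8
C,3D-CRT,90,180,22.1
C,3D-CRT,90,270,18.9
C,IMRT,90,0,45
C,IMRT,90,90,31.6
C,IMRT,90,180,10.7
C,IMRT,90,270,12.7
C,VMAT,90,0,27.4
C,VMAT,90,90,28.2
C,VMAT,90,180,20.9
C,VMAT,90,270,23.5
C,Total,90,0,29.1
C,Total,90,90,35.9
C,Total,90,180,16.5
C,Total,90,270,18.5
A-1,3D-CRT,45,0,12
A-1,3D-CRT,45,45,4.1
A-1,3D-CRT,45,90,17.1
A-1,3D-CRT,45,135,14.3
A-1,3D-CRT,45,180,14.2
A-1,3D-CRT,45,225,15.2
A-1,3D-CRT,45,270,18
A-1,3D-CRT,45,315,5.1
A-1,VMAT,45,0,13.5
A-1,VMAT,45,45,12.7
A-1,VMAT,45,90,12.2
A-1,VMAT,45,135,11.8
A-1,VMAT,45,180,10.7
A-1,VMAT,45,225,13.3
A-1,VMAT,45,270,13.5
A-1,VMAT,45,315,12.4
A-1,Total,45,0,13.2
A-1,Total,45,45,11.9
A-1,Total,45,90,12.8
A-1,Total,45,135,12.2
A-1,Total,45,180,11.4
A-1,Total,45,225,13.2
A-1,Total,45,270,13.4
A-1,Total,45,315,11.9
A-2,3D-CRT,45,0,20.6
A-2,3D-CRT,45,45,7.6
A-2,3D-CRT,45,90,11.3
A-2,3D-CRT,45,135,15.8
A-2,3D-CRT,45,180,11.6
A-2,3D-CRT,45,225,9.4
A-2,3D-CRT,45,270,11
A-2,3D-CRT,45,315,12.8
A-2,VMAT,45,0,13.1
A-2,VMAT,45,45,14
A-2,VMAT,45,90,11.6
A-2,VMAT,45,135,9.8
A-2,VMAT,45,180,9.6
A-2,VMAT,45,225,13.6
A-2,VMAT,45,270,15.5
A-2,VMAT,45,315,12.8
A-2,Total,45,0,13.4
A-2,Total,45,45,13.5
A-2,Total,45,90,11.3
A-2,Total,45,135,10.6
A-2,Total,45,180,9.8
A-2,Total,45,225,13.4
A-2,Total,45,270,15.1
A-2,Total,45,315,12.9
B,3D-CRT,45,0,20.6
B,3D-CRT,45,45,10.5
B,3D-CRT,45,90,6.1
B,3D-CRT,45,135,13.8
B,3D-CRT,45,180,17.4
B,3D-CRT,45,225,13.6
B,3D-CRT,45,270,6.4
B,3D-CRT,45,315,11.6
B,IMRT,45,0,13.6
B,IMRT,45,45,19.1
B,IMRT,45,90,6.2
B,IMRT,45,135,11.4
B,IMRT,45,180,10.2
B,IMRT,45,225,14.4
B,IMRT,45,270,9.8
B,IMRT,45,315,15.3
B,VMAT,45,0,13.9
B,VMAT,45,45,13.2
B,VMAT,45,90,11.1
B,VMAT,45,135,11.2
B,VMAT,45,180,13.1
B,VMAT,45,225,12.5
B,VMAT,45,270,11.7
B,VMAT,45,315,13.3
B,Total,45,0,13.6
B,Total,45,45,16.2
B,Total,45,90,8.1
B,Total,45,135,11.5
B,Total,45,180,12.1
B,Total,45,225,14
B,Total,45,270,10.2
B,Total,45,315,14.4
C,3D-CRT,45,0,19.1
C,3D-CRT,45,45,14.2
C,3D-CRT,45,90,20.6
C,3D-CRT,45,135,4.2
C,3D-CRT,45,180,17.9
C,3D-CRT,45,225,5.6
C,3D-CRT,45,270,13.3
C,3D-CRT,45,315,5.2
C,IMRT,45,0,28.5
C,IMRT,45,45,21.1
C,IMRT,45,90,10.5
C,IMRT,45,135,4.8
C,IMRT,45,180,5.9
C,IMRT,45,225,5.3
C,IMRT,45,270,7.4
C,IMRT,45,315,16.5
C,VMAT,45,0,14.2
C,VMAT,45,45,13.9
C,VMAT,45,90,14.3
C,VMAT,45,135,11.9
C,VMAT,45,180,9
C,VMAT,45,225,10.3
C,VMAT,45,270,13.2
C,VMAT,45,315,13.2
C,Total,45,0,17
C,Total,45,45,19.3
C,Total,45,90,16.5
C,Total,45,135,8.3
C,Total,45,180,8.2
C,Total,45,225,7.3
C,Total,45,270,11.3
C,Total,45,315,12.1
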